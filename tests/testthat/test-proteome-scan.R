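test_that("FASTA reading sanitizes records and flags defects", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1 first toy", "mkvh", "apy", ">At4g01160.2", "ACDEFGH"), fa)
  recs <- read_fasta(fa)
  expect_equal(recs$seq_id, c("s1", "At4g01160.2"))
  expect_equal(recs$description, c("first toy", ""))
  expect_equal(recs$sequence, c("MKVHAPY", "ACDEFGH"))

  writeLines(c(">aln", "AC-DE..F"), fa)
  expect_warning(recs <- read_fasta(fa), "alignment characters")
  expect_equal(recs$sequence, "ACDEF")

  writeLines(">only_header", fa)
  expect_error(read_fasta(fa), "empty sequence")

  writeLines(c(">dup", "AAA", ">dup", "CCC"), fa)
  expect_message(read_fasta(fa), "duplicate")

  expect_error(read_fasta(tempfile()), "not found")
})

test_that("the scanner reproduces hand-derived realizations", {
  strict <- parse_motif(STRICT_MOTIF)

  m <- find_matches(strict, toy_strict_seq())
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 2L)
  expect_equal(m$end, 36L)
  expect_equal(m$gaps, "12,16,1,1")

  # shorter than min_span: no match
  expect_equal(nrow(find_matches(strict, strrep("A", 30))), 0L)

  # two H anchors whose gap choices land on one shared YxSxR block
  twin <- paste0("HH", strrep("A", 11), "PP", strrep("A", 14), "YASAR")
  m2 <- find_matches(strict, twin)
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$start, c(1L, 2L))
  expect_equal(unique(m2$end), 34L)
  expect_equal(m2$gaps, c("12,15,1,1", "12,14,1,1"))

  # leftmost-shortest policy keeps one realization per anchor
  m3 <- find_matches(strict, twin, policy = "LEFTMOST_SHORTEST_PER_ANCHOR")
  expect_equal(nrow(m3), 2L)
  expect_equal(m3$start, c(1L, 2L))
})

test_that("matches never cross '*' segment breaks and keep global coordinates", {
  strict <- parse_motif(STRICT_MOTIF)
  shifted <- paste0("AAA*", toy_strict_seq())
  m <- find_matches(strict, shifted)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 6L)
  expect_equal(m$end, 40L)

  # the same characters with a stop inside the span: no match
  broken <- paste0("M", "H", strrep("A", 6), "*", strrep("A", 5), "P",
                   strrep("A", 16), "YASAR")
  expect_equal(nrow(find_matches(strict, broken)), 0L)
})

test_that("non-standard residue codes fill gaps but never fixed positions", {
  m <- parse_motif("Hx(2)R")
  expect_equal(nrow(find_matches(m, "HXBR")), 1L)   # X/B inside the gap
  expect_equal(nrow(find_matches(m, "HAAX")), 0L)   # X cannot satisfy R
  expect_equal(nrow(find_matches(m, "UAAR")), 0L)   # U cannot satisfy H
  expect_error(parse_motif("HxX"), "anchored")      # X is the gap symbol
})

test_that("all-realization scanning equals the brute-force oracle", {
  set.seed(101)
  motifs <- list(parse_motif("Ax(1,3)Dx(2)C"), parse_motif("AxD"),
                 parse_motif("Ax(2,5)D"), parse_motif("CxAx(1,2)C"))
  n_checked <- 0L
  for (i in 1:200) {
    s <- rand_seq(sample(10:60, 1L), c("A", "B", "C", "D"))
    for (m in motifs) {
      got <- find_matches(m, s)
      want <- brute_force_matches(m, s)
      expect_equal(match_key(got), match_key(want))
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 800L)
})

test_that("key residues map to verified, strictly increasing positions", {
  strict <- parse_motif(STRICT_MOTIF)
  toy <- toy_strict_seq()
  m <- find_matches(strict, toy)
  keys <- map_key_residues(m[1L, ], strict, toy)
  expect_equal(keys, c(H = 2L, P = 15L, Y = 32L, S = 34L, R = 36L))
  expect_true(all(diff(keys) > 0))

  single <- find_matches(parse_motif("H"), "AAHA")
  expect_equal(map_key_residues(single[1L, ], parse_motif("H")), c(H = 3L))

  # inconsistent pairing: realized gaps violate the other motif's bounds
  expect_error(map_key_residues(m[1L, ], parse_motif("Hx(2)PxYxSxR")),
               "mismatch")
  # duplicated fixed letters get ordinals
  hh <- find_matches(parse_motif("HxH"), "HAH")
  expect_equal(names(map_key_residues(hh[1L, ], parse_motif("HxH"))),
               c("H1", "H2"))
})

test_that("residue enumeration within a span is exact", {
  expect_equal(residues_in_span("ACCA", c(1, 4), "C"), c(2L, 3L))
  expect_equal(residues_in_span("ACCA", c(1, 4), "W"), integer())
  expect_equal(residues_in_span("ACCA", c(3, 4), "C"), 3L)
  expect_error(residues_in_span("ACCA", c(0, 4), "C"), "out of range")
  expect_error(residues_in_span("ACCA", c(2, 9), "C"), "out of range")
})

test_that("strict-motif matches are a subset of relaxed-motif matches", {
  strict <- parse_motif(STRICT_MOTIF)
  relaxed <- parse_motif(RELAXED_MOTIF)
  set.seed(202)
  n_with_hits <- 0L
  for (i in 1:60) {
    # random 20-letter background with a planted strict realization
    bg <- strsplit(rand_seq(60, AA_letters()), "")[[1]]
    g2 <- sample(14:16, 1L)
    real <- strsplit(paste0("H", rand_seq(12, AA_letters()), "P",
                            rand_seq(g2, AA_letters()), "Y",
                            rand_seq(1, AA_letters()), "S",
                            rand_seq(1, AA_letters()), "R"), "")[[1]]
    at <- sample(seq_len(60 - length(real) + 1L), 1L)
    bg[at:(at + length(real) - 1L)] <- real
    s <- paste(bg, collapse = "")
    ms <- find_matches(strict, s)
    mr <- find_matches(relaxed, s)
    expect_true(all(paste(ms$start, ms$end) %in% paste(mr$start, mr$end)))
    if (nrow(ms)) n_with_hits <- n_with_hits + 1L
    # spans of either motif stay within [33, 35]
    expect_true(all((ms$end - ms$start + 1) %in% 33:35))
    expect_true(all((mr$end - mr$start + 1) %in% 33:35))
  }
  expect_gte(n_with_hits, 55L)  # planting makes strict hits near-certain
})

test_that("proteome scanning aggregates deterministically and collapses loci", {
  strict <- parse_motif(STRICT_MOTIF)
  recs <- data.frame(
    seq_id = c("At4g01160.1", "At4g01160.2", "myseq", "At1g62580.1"),
    description = "",
    sequence = c(toy_strict_seq(), toy_strict_seq(), toy_strict_seq(),
                 strrep("A", 40)),
    stringsAsFactors = FALSE)
  ms <- scan_proteome(strict, recs)
  expect_equal(ms$n_records, 4L)
  expect_equal(ms$n_matching_records, 3L)
  expect_equal(ms$n_realizations, 3L)

  cand <- collapse_to_loci(ms)
  expect_equal(cand$locus, c("AT4G01160", "myseq"))
  expect_equal(cand$n_gene_models[1L], 2L)
  expect_equal(cand$gene_models[1L], "At4g01160.1,At4g01160.2")
  expect_equal(sum(cand$n_gene_models), ms$n_matching_records)

  tab <- match_table(ms)
  expect_equal(tab$pos_H, rep(2L, 3L))
  expect_equal(tab$pos_R, rep(36L, 3L))

  # re-scan is byte-identical
  expect_identical(ms$matches, scan_proteome(strict, recs)$matches)
})
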