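#' Read a protein FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-record protein FASTA via
#' \pkg{Biostrings} and returns plain records ready for scanning. Sequences
#' are upper-cased; whitespace and digits are dropped by the reader;
#' alignment characters \code{"-"} and \code{"."} are stripped with a
#' warning. Internal \code{"*"} terminators are kept: the scanner treats
#' them as hard segment breaks so no match ever crosses a stop.
#'
#' @param path Path to a FASTA file.
#' @return A data frame of class \code{"hnox_records"} with columns
#'   \code{seq_id} (first whitespace-delimited token of the header),
#'   \code{description} (remainder of the header) and \code{sequence}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- suppressWarnings(Biostrings::readAAStringSet(path))
  if (length(aa) == 0L) stop("no FASTA records in ", path)
  hdr <- names(aa)
  seq_id <- sub("\\s.*$", "", hdr)
  description <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  sequence <- toupper(as.character(aa))
  if (any(grepl("[-.]", sequence))) {
    warning("stripping alignment characters '-'/'.' from ",
            sum(grepl("[-.]", sequence)), " record(s)")
    sequence <- gsub("[-.]", "", sequence)
  }
  empty <- !nzchar(gsub("\\*", "", sequence))
  if (any(empty))
    stop("record(s) with empty sequence after sanitation: ",
         paste(seq_id[empty], collapse = ", "))
  if (anyDuplicated(seq_id))
    message("duplicate sequence IDs in ", path, ": ",
            paste(unique(seq_id[duplicated(seq_id)]), collapse = ", "))
  structure(data.frame(seq_id = seq_id, description = description,
                       sequence = sequence, stringsAsFactors = FALSE),
            class = c("hnox_records", "data.frame"))
}

#' Write protein records to FASTA
#'
#' @param records A data frame with \code{seq_id}, \code{description} and
#'   \code{sequence} columns (as from [read_fasta()] or [gen_proteome()]).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- ifelse(nzchar(records$description),
                      paste(records$seq_id, records$description),
                      records$seq_id)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

as_protein_record <- function(record) {
  if (is.character(record) && length(record) == 1L) {
    record <- data.frame(seq_id = if (!is.null(names(record))) names(record)
                         else "seq1",
                         description = "", sequence = toupper(record),
                         stringsAsFactors = FALSE)
  }
  if (is.list(record) && !is.data.frame(record))
    record <- data.frame(seq_id = record$seq_id, description = "",
                         sequence = toupper(record$sequence),
                         stringsAsFactors = FALSE)
  stopifnot(is.data.frame(record), nrow(record) == 1L,
            all(c("seq_id", "sequence") %in% names(record)))
  record
}

empty_matches <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             gaps = character(), stringsAsFactors = FALSE)
}

#' Find all realizations of a motif on one protein sequence
#'
#' Enumerates every way the motif can be laid onto the sequence: an anchor
#' position for the first fixed residue plus a choice of length for each gap
#' token such that all fixed residues agree with the sequence. Matching is
#' exact on fixed residues: non-standard letters (X, B, Z, U, O) in the
#' sequence may fill gap positions but never satisfy a fixed token. Segments
#' delimited by internal \code{"*"} terminators are scanned independently,
#' so matches never span a stop.
#'
#' @param motif An \code{"hnox_motif"} (or a motif string).
#' @param record A single protein record (one-row data frame from
#'   [read_fasta()], a \code{list(seq_id=, sequence=)}, or a bare sequence
#'   string).
#' @param policy \code{"ALL_REALIZATIONS"} (default) reports every distinct
#'   \code{(start, end, gap_lengths)}; \code{"LEFTMOST_SHORTEST_PER_ANCHOR"}
#'   keeps, for each anchor start, only the realization with the
#'   lexicographically smallest gap-length vector.
#' @return A data frame with columns \code{seq_id}, \code{start}, \code{end}
#'   (1-based inclusive residue coordinates) and \code{gaps} (comma-joined
#'   realized gap lengths), ordered by \code{(start, end, gaps)}.
#' @export
find_matches <- function(motif, record,
                         policy = c("ALL_REALIZATIONS",
                                    "LEFTMOST_SHORTEST_PER_ANCHOR")) {
  motif <- as_motif(motif)
  policy <- match.arg(policy)
  record <- as_protein_record(record)
  tk <- motif$tokens
  chars <- strsplit(record$sequence, "")[[1]]

  # segment at "*" stops
  stops <- which(chars == "*")
  seg_start <- c(1L, stops + 1L)
  seg_end <- c(stops - 1L, length(chars))
  out <- empty_matches()
  grid <- gap_length_grid(tk)
  fixed_idx <- which(tk$kind == "FIXED")
  for (s in seq_along(seg_start)) {
    if (seg_end[s] < seg_start[s]) next
    seg <- chars[seg_start[s]:seg_end[s]]
    hits <- scan_segment(tk, grid, fixed_idx, seg)
    if (nrow(hits)) {
      hits$start <- hits$start + seg_start[s] - 1L
      hits$end <- hits$end + seg_start[s] - 1L
      hits$seq_id <- record$seq_id
      out <- rbind(out, hits[, c("seq_id", "start", "end", "gaps")])
    }
  }
  if (nrow(out)) {
    gv <- gaps_matrix(out$gaps)
    ord <- do.call(order, c(list(out$start, out$end),
                            as.data.frame(gv)))
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    if (policy == "LEFTMOST_SHORTEST_PER_ANCHOR") {
      gv <- gaps_matrix(out$gaps)
      ord2 <- do.call(order, c(list(out$start), as.data.frame(gv)))
      out <- out[ord2, , drop = FALSE]
      out <- out[!duplicated(out$start), , drop = FALSE]
      out <- out[order(out$start, out$end), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

gaps_matrix <- function(gaps) {
  if (length(gaps) == 0L) return(matrix(integer(), 0L, 0L))
  lst <- lapply(strsplit(gaps, ",", fixed = TRUE), as.integer)
  n <- max(lengths(lst), 1L)
  matrix(unlist(lapply(lst, function(g) {
    length(g) <- n
    g
  })), nrow = length(lst), ncol = n, byrow = TRUE)
}

# Scan one stop-free segment; coordinates local to the segment.
scan_segment <- function(tk, grid, fixed_idx, seg) {
  n <- length(seg)
  out <- empty_matches()
  anchors0 <- which(seg == tk$residue[1L])
  if (length(anchors0) == 0L) return(out)
  for (r in seq_len(max(nrow(grid), 1L))) {
    g <- as.integer(grid[r, ])
    lens <- ifelse(tk$kind == "FIXED", 1L, 0L)
    lens[tk$kind == "GAP"] <- g
    offs <- cumsum(c(0L, lens[-length(lens)]))[fixed_idx]
    total <- sum(lens)
    anchors <- anchors0[anchors0 + total - 1L <= n]
    if (length(anchors) == 0L) next
    ok <- rep(TRUE, length(anchors))
    for (k in seq_along(fixed_idx)[-1L]) {
      ok <- ok & seg[anchors + offs[k]] == tk$residue[fixed_idx[k]]
      if (!any(ok)) break
    }
    if (any(ok)) {
      st <- anchors[ok]
      out <- rbind(out, data.frame(
        seq_id = NA_character_, start = st, end = st + total - 1L,
        gaps = paste(g, collapse = ","), stringsAsFactors = FALSE))
    }
  }
  out
}

#' Map the fixed residues of a match to sequence positions
#'
#' Given a match realization and the motif that produced it, returns the
#' 1-based sequence position of every fixed residue, named by its letter
#' (with an ordinal appended when a letter occurs more than once among the
#' fixed tokens). For the strict H-NOX motif anchored at H357 with maximal
#' gaps this reproduces H357, P370, Y387, S389, R391.
#'
#' @param match A one-row match data frame from [find_matches()].
#' @param motif The \code{"hnox_motif"} the match was produced from.
#' @param record Optional: the protein record, used to verify that each
#'   mapped position actually carries the token's residue letter.
#' @return Named integer vector of positions, in motif order.
#' @export
map_key_residues <- function(match, motif, record = NULL) {
  motif <- as_motif(motif)
  stopifnot(is.data.frame(match), nrow(match) == 1L)
  tk <- motif$tokens
  g <- as.integer(strsplit(match$gaps, ",", fixed = TRUE)[[1]])
  if (length(g) != sum(tk$kind == "GAP"))
    stop("match/motif mismatch: match has ", length(g),
         " gap lengths but motif has ", sum(tk$kind == "GAP"), " gap tokens")
  if (any(g < tk$min[tk$kind == "GAP"]) || any(g > tk$max[tk$kind == "GAP"]))
    stop("match/motif mismatch: realized gap lengths violate the motif's bounds")
  lens <- ifelse(tk$kind == "FIXED", 1L, 0L)
  lens[tk$kind == "GAP"] <- g
  fixed_idx <- which(tk$kind == "FIXED")
  pos <- as.integer(match$start) + cumsum(c(0L, lens[-length(lens)]))[fixed_idx]
  letters_ <- tk$residue[fixed_idx]
  nm <- letters_
  if (anyDuplicated(letters_))
    nm <- paste0(letters_, seq_along(letters_))
  names(pos) <- nm
  if (!is.null(record)) {
    record <- as_protein_record(record)
    chars <- strsplit(record$sequence, "")[[1]]
    bad <- chars[pos] != letters_
    if (any(bad))
      stop("match/record mismatch: position ", pos[bad][1L], " carries ",
           chars[pos[bad][1L]], ", expected ", letters_[bad][1L])
  }
  pos
}

#' Positions of a residue within a span of a sequence
#'
#' Used to enumerate, e.g., cysteines inside a matched H-NOX center that are
#' candidate S-nitrosylation sites.
#'
#' @param record A protein record (see [find_matches()]).
#' @param span Integer vector \code{c(start, end)}, 1-based inclusive.
#' @param letter One-letter residue code.
#' @return Ascending integer positions \code{p} in \code{[start, end]} with
#'   \code{sequence[p] == letter}.
#' @export
residues_in_span <- function(record, span, letter) {
  record <- as_protein_record(record)
  chars <- strsplit(record$sequence, "")[[1]]
  span <- as.integer(span)
  if (length(span) != 2L || span[1L] < 1L || span[2L] > length(chars) ||
      span[1L] > span[2L])
    stop("span (", span[1L], ",", span[2L], ") out of range for sequence of ",
         length(chars), " residues")
  idx <- span[1L]:span[2L]
  idx[chars[idx] == toupper(letter)]
}

#' Scan a set of protein records with a motif
#'
#' Applies [find_matches()] to every record, preserving input record order,
#' and tallies matching sequences and realizations. Scanning is fully
#' deterministic.
#'
#' @param motif An \code{"hnox_motif"} (or motif string).
#' @param records Data frame of protein records (from [read_fasta()] or
#'   [gen_proteome()]).
#' @param policy Match policy, see [find_matches()].
#' @return An object of class \code{"hnox_matchset"}: list with
#'   \code{matches} (combined match data frame), \code{motif},
#'   \code{policy}, \code{n_records}, \code{n_matching_records},
#'   \code{n_realizations} and \code{per_record} (named realization counts
#'   for matching records).
#' @export
scan_proteome <- function(motif, records,
                          policy = c("ALL_REALIZATIONS",
                                     "LEFTMOST_SHORTEST_PER_ANCHOR")) {
  motif <- as_motif(motif)
  policy <- match.arg(policy)
  stopifnot(is.data.frame(records))
  parts <- lapply(seq_len(nrow(records)), function(i)
    find_matches(motif, records[i, , drop = FALSE], policy))
  matches <- do.call(rbind, c(list(empty_matches()), parts))
  rownames(matches) <- NULL
  tallies <- table(factor(matches$seq_id, levels = unique(matches$seq_id)))
  structure(list(matches = matches, motif = motif, policy = policy,
                 n_records = nrow(records),
                 n_matching_records = length(unique(matches$seq_id)),
                 n_realizations = nrow(matches),
                 per_record = tallies),
            class = "hnox_matchset")
}

#' @export
print.hnox_matchset <- function(x, ...) {
  cat("Motif scan: ", format_motif(x$motif), " (", x$policy, ")\n", sep = "")
  cat("  ", x$n_matching_records, " of ", x$n_records,
      " sequences matched; ", x$n_realizations, " realization(s)\n", sep = "")
  if (x$n_realizations > 0L) {
    print(utils::head(x$matches, 10L))
    if (x$n_realizations > 10L) cat("  ...\n")
  }
  invisible(x)
}

# An AGI gene-model identifier, e.g. At4g01160.2 (chromosomes 1-5 plus the
# mitochondrial/chloroplast codes), with optional isoform suffix.
is_agi_id <- function(id) {
  grepl("^A[Tt][1-5CMcm][Gg][0-9]{5}(\\.[0-9]+)?$", id)
}

normalize_locus <- function(id) {
  ifelse(is_agi_id(id), toupper(sub("\\.[0-9]+$", "", id)), id)
}

#' Collapse a match set to locus-level candidates
#'
#' AGI gene-model identifiers (e.g. \code{At4g01160.1}, \code{At4g01160.2})
#' are normalized by upper-casing and stripping the trailing gene-model
#' suffix, so isoforms of one locus are reported as a single candidate.
#' Non-AGI identifiers are grouped verbatim. Candidate counting uses
#' distinct sequence IDs, so realization multiplicity never inflates the
#' gene-model count.
#'
#' @param matchset An \code{"hnox_matchset"} from [scan_proteome()] (or a
#'   bare match data frame).
#' @return A data frame of class \code{"hnox_candidates"}, one row per
#'   locus, sorted by locus: columns \code{locus}, \code{gene_models}
#'   (comma-joined matching seq_ids), \code{n_gene_models},
#'   \code{n_matches} (realizations) and \code{spans}
#'   (semicolon-joined \code{start-end}).
#' @export
collapse_to_loci <- function(matchset) {
  matches <- if (inherits(matchset, "hnox_matchset")) matchset$matches
             else matchset
  if (nrow(matches) == 0L) {
    out <- data.frame(locus = character(), gene_models = character(),
                      n_gene_models = integer(), n_matches = integer(),
                      spans = character(), stringsAsFactors = FALSE)
    class(out) <- c("hnox_candidates", "data.frame")
    return(out)
  }
  locus <- normalize_locus(matches$seq_id)
  rows <- lapply(split(seq_len(nrow(matches)), locus), function(i) {
    data.frame(
      locus = locus[i[1L]],
      gene_models = paste(unique(matches$seq_id[i]), collapse = ","),
      n_gene_models = length(unique(matches$seq_id[i])),
      n_matches = length(i),
      spans = paste(paste0(matches$start[i], "-", matches$end[i]),
                    collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$locus), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hnox_candidates", "data.frame")
  out
}

#' Full match table with key-residue columns
#'
#' Expands a match set into a flat table suitable for TSV export: one row
#' per realization with locus, 1-based inclusive coordinates, realized gap
#' lengths and one position column per fixed motif residue.
#'
#' @param matchset An \code{"hnox_matchset"} from [scan_proteome()].
#' @return A data frame.
#' @export
match_table <- function(matchset) {
  stopifnot(inherits(matchset, "hnox_matchset"))
  matches <- matchset$matches
  if (nrow(matches) == 0L) {
    return(cbind(data.frame(seq_id = character(), locus = character()),
                 matches[, c("start", "end", "gaps")]))
  }
  keys <- t(vapply(seq_len(nrow(matches)), function(i)
    map_key_residues(matches[i, , drop = FALSE], matchset$motif),
    map_key_residues(matches[1L, , drop = FALSE], matchset$motif)))
  colnames(keys) <- paste0("pos_", colnames(keys))
  cbind(data.frame(seq_id = matches$seq_id,
                   locus = normalize_locus(matches$seq_id),
                   stringsAsFactors = FALSE),
        matches[, c("start", "end", "gaps")],
        as.data.frame(keys))
}
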