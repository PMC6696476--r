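# Independent oracles and fixture builders used across the suite.

# Brute-force motif matcher: tries every (start, gap-length-vector)
# combination with a simple per-token walk. Deliberately naive and
# independent of the scanner's anchor/vectorized implementation.
brute_force_matches <- function(motif, seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  tk <- motif$tokens
  gi <- which(tk$kind == "GAP")
  combos <- if (length(gi))
    expand.grid(lapply(gi, function(i) tk$min[i]:tk$max[i]))
  else data.frame(row.names = 1)
  res <- NULL
  for (start in seq_along(chars)) {
    for (r in seq_len(max(nrow(combos), 1L))) {
      g <- as.integer(combos[r, ])
      pos <- start
      ok <- TRUE
      gidx <- 0L
      for (t in seq_len(nrow(tk))) {
        if (tk$kind[t] == "FIXED") {
          if (pos > length(chars) || chars[pos] != tk$residue[t]) {
            ok <- FALSE; break
          }
          pos <- pos + 1L
        } else {
          gidx <- gidx + 1L
          if (pos + g[gidx] - 1L > length(chars)) { ok <- FALSE; break }
          if (any(chars[pos:(pos + g[gidx] - 1L)] == "*")) { ok <- FALSE; break }
          pos <- pos + g[gidx]
        }
      }
      if (ok)
        res <- rbind(res, data.frame(start = start, end = pos - 1L,
                                     gaps = paste(g, collapse = ","),
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(res))
    return(data.frame(start = integer(), end = integer(),
                      gaps = character(), stringsAsFactors = FALSE))
  gv <- do.call(rbind, lapply(strsplit(res$gaps, ","), as.integer))
  res[do.call(order, c(list(res$start, res$end), as.data.frame(gv))), ,
      drop = FALSE]
}

match_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  paste(df$start, df$end, df$gaps)
}

rand_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Random small anchored motif over a restricted fixed-residue alphabet.
rand_motif <- function(alphabet = c("A", "C", "D", "E"), max_gaps = 2L) {
  n_fixed <- sample(2:4, 1L)
  letters_ <- sample(alphabet, n_fixed, replace = TRUE)
  parts <- letters_[1L]
  for (k in seq_len(n_fixed - 1L)) {
    lo <- sample(1:3, 1L)
    hi <- lo + sample(0:2, 1L)
    gap <- if (lo == 1L && hi == 1L) "x"
           else if (lo == hi) sprintf("x(%d)", lo)
           else sprintf("x(%d,%d)", lo, hi)
    parts <- c(parts, gap, letters_[k + 1L])
  }
  parse_motif(paste(parts, collapse = ""))
}

# Alignment whose rows realize the motif at its extreme gap vectors, with
# gap residues left-justified and "-" padding on the right; critical
# columns are the fixed-token columns of the full-width layout.
make_extreme_alignment <- function(m, fill = "A") {
  tk <- m$tokens
  gi <- which(tk$kind == "GAP")
  vecs <- list(tk$min[gi], tk$max[gi])
  for (k in seq_along(gi)) {
    v <- tk$min[gi]
    v[k] <- tk$max[gi][k]
    vecs <- c(vecs, list(v))
  }
  vecs <- unique(vecs)
  widths <- ifelse(tk$kind == "FIXED", 1L, 0L)
  widths[gi] <- tk$max[gi]
  startcol <- cumsum(c(1L, widths[-length(widths)]))
  crit <- startcol[tk$kind == "FIXED"]
  rows <- vapply(vecs, function(v) {
    out <- character(0)
    gidx <- 0L
    for (t in seq_len(nrow(tk))) {
      if (tk$kind[t] == "FIXED") out <- c(out, tk$residue[t])
      else {
        gidx <- gidx + 1L
        out <- c(out, rep(fill, v[gidx]), rep("-", tk$max[t] - v[gidx]))
      }
    }
    paste(out, collapse = "")
  }, character(1))
  center_alignment(stats::setNames(rows, paste0("r", seq_along(rows))), crit)
}

expected_state <- function(template_name) {
  switch(template_name,
         ferric = "FERRIC_HIS_LIGATED", ferrous = "FERROUS_6C",
         no_5c = "FERROUS_5C_NO", hemin = "FREE_HEMIN",
         apo = "APO_NO_HEME")
}

AA_letters <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

STRICT_MOTIF <- "Hx(12)Px(14,16)YxSxR"
RELAXED_MOTIF <- "Hx(27,29)YxSxR"

# 36-mer with exactly one strict-motif realization at positions 2-36.
toy_strict_seq <- function() {
  paste0("M", "H", strrep("A", 12), "P", strrep("A", 16), "YASAR")
}
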