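# The 20 standard amino-acid one-letter codes. "X" is reserved by the motif
# grammar as the gap symbol and degenerate codes (B, Z, J, U, O) are not
# permitted at fixed positions.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

new_motif <- function(tokens, source_text = NA_character_) {
  rownames(tokens) <- NULL
  structure(list(tokens = tokens, source_text = source_text),
            class = "hnox_motif")
}

motif_tokens <- function(kind = character(), residue = character(),
                         min = integer(), max = integer()) {
  data.frame(kind = kind, residue = residue,
             min = as.integer(min), max = as.integer(max),
             stringsAsFactors = FALSE)
}

#' Parse a flexible-gap protein motif
#'
#' Parses motif strings in the PROSITE-like dialect used for H-NOX center
#' searches: fixed one-letter residues interleaved with bounded wildcard
#' gaps, e.g. \code{"Hx(12)Px(14,16)YxSxR"}. \code{"x"} denotes a gap of
#' exactly one residue, \code{"x(n)"} a gap of exactly \code{n} and
#' \code{"x(n,m)"} a gap of between \code{n} and \code{m} residues.
#'
#' Parsing is case-insensitive. The result is canonical: adjacent gap tokens
#' are merged by summing their bounds, and both the first and last token must
#' be fixed residues (the motif is anchored). Fixed residues must be one of
#' the 20 standard amino-acid letters; \code{X} always means a gap.
#'
#' @param text A single motif string.
#' @return An object of class \code{"hnox_motif"}: a list with elements
#'   \code{tokens} (data frame with columns \code{kind} (\code{"FIXED"} or
#'   \code{"GAP"}), \code{residue}, \code{min}, \code{max}) and
#'   \code{source_text}.
#' @examples
#' m <- parse_motif("Hx(12)Px(14,16)YxSxR")
#' format_motif(relax(m, 3))   # drop the proline
#' span_bounds(m)
#' @seealso [format_motif()], [relax()], [span_bounds()]
#' @export
parse_motif <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single motif string")
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) stop("empty motif string")

  pat <- "[A-Za-z](\\(\\d+(,\\d+)?\\))?"
  m <- gregexpr(pat, text)[[1]]
  raw <- regmatches(text, gregexpr(pat, text))[[1]]
  if (length(raw) == 0L || sum(attr(m, "match.length")) != nchar(text))
    stop("malformed motif string: ", sQuote(text))

  toks <- motif_tokens()
  for (tk in raw) {
    letter <- toupper(substr(tk, 1L, 1L))
    has_bounds <- nchar(tk) > 1L
    if (letter == "X") {
      if (has_bounds) {
        nums <- as.integer(strsplit(gsub("[()]", "", substring(tk, 2L)),
                                    ",", fixed = TRUE)[[1]])
        lo <- nums[1L]
        hi <- if (length(nums) == 2L) nums[2L] else nums[1L]
        if (lo < 1L)
          stop("gap token ", sQuote(tk), " has zero lower bound; gaps span at least one residue")
        if (hi < lo)
          stop("gap token ", sQuote(tk), " has inverted bounds (max < min)")
      } else {
        lo <- hi <- 1L
      }
      toks <- rbind(toks, motif_tokens("GAP", NA_character_, lo, hi))
    } else {
      if (has_bounds)
        stop("length bounds are only allowed on gap tokens: ", sQuote(tk))
      if (!letter %in% AA_STANDARD)
        stop("unknown residue letter ", sQuote(letter),
             " in token ", sQuote(tk),
             "; fixed positions use the 20 standard amino-acid codes")
      toks <- rbind(toks, motif_tokens("FIXED", letter, 1L, 1L))
    }
  }

  if (toks$kind[1L] == "GAP")
    stop("motif starts with a gap token ", sQuote(raw[1L]),
         "; motifs must be anchored by fixed residues")
  if (toks$kind[nrow(toks)] == "GAP")
    stop("motif ends with a gap token ", sQuote(raw[length(raw)]),
         "; motifs must be anchored by fixed residues")

  new_motif(merge_adjacent_gaps(toks), text)
}

merge_adjacent_gaps <- function(toks) {
  keep <- rep(TRUE, nrow(toks))
  i <- 2L
  while (i <= nrow(toks)) {
    if (toks$kind[i] == "GAP") {
      j <- max(which(keep[seq_len(i - 1L)]))
      if (toks$kind[j] == "GAP") {
        toks$min[j] <- toks$min[j] + toks$min[i]
        toks$max[j] <- toks$max[i] + toks$max[j]
        keep[i] <- FALSE
      }
    }
    i <- i + 1L
  }
  toks[keep, , drop = FALSE]
}

#' Serialize a motif to its canonical string form
#'
#' Inverse of [parse_motif()] on canonical motifs: \code{gap(1,1)} prints as
#' \code{"x"}, \code{gap(n,n)} as \code{"x(n)"} and \code{gap(n,m)} as
#' \code{"x(n,m)"}.
#'
#' @param motif An \code{"hnox_motif"} object.
#' @return A single character string.
#' @export
format_motif <- function(motif) {
  stopifnot(inherits(motif, "hnox_motif"))
  tk <- motif$tokens
  out <- character(nrow(tk))
  for (i in seq_len(nrow(tk))) {
    out[i] <- if (tk$kind[i] == "FIXED") tk$residue[i]
    else if (tk$min[i] == 1L && tk$max[i] == 1L) "x"
    else if (tk$min[i] == tk$max[i]) sprintf("x(%d)", tk$min[i])
    else sprintf("x(%d,%d)", tk$min[i], tk$max[i])
  }
  paste(out, collapse = "")
}

#' @export
format.hnox_motif <- function(x, ...) format_motif(x)

#' @export
print.hnox_motif <- function(x, ...) {
  tk <- x$tokens
  cat("Flexible-gap motif: ", format_motif(x), "\n", sep = "")
  cat("  ", nrow(tk), " tokens (", sum(tk$kind == "FIXED"), " fixed, ",
      sum(tk$kind == "GAP"), " gap); span ",
      sum(tk$min), "-", sum(tk$max), " residues\n", sep = "")
  invisible(x)
}

#' Minimum and maximum span of a motif
#'
#' The span is the number of residues a full realization of the motif
#' occupies on a sequence; its bounds are the sums of the per-token length
#' bounds (fixed residues count 1).
#'
#' @param motif An \code{"hnox_motif"} object.
#' @return Named integer vector \code{c(min_span, max_span)}.
#' @export
span_bounds <- function(motif) {
  stopifnot(inherits(motif, "hnox_motif"))
  c(min_span = sum(motif$tokens$min), max_span = sum(motif$tokens$max))
}

#' Relax a motif by dropping an interior fixed residue
#'
#' Replaces the fixed token at \code{token_index} by a one-residue gap and
#' merges it with any adjacent gaps by summing their bounds. This widens the
#' motif's language (every sequence matched before is still matched) while
#' preserving its span bounds. Dropping the proline from
#' \code{"Hx(12)Px(14,16)YxSxR"} yields \code{"Hx(27,29)YxSxR"}.
#'
#' @param motif An \code{"hnox_motif"} object.
#' @param token_index Index (into \code{motif$tokens}) of an interior FIXED
#'   token. The first and last tokens are anchors and cannot be relaxed.
#' @return The relaxed canonical \code{"hnox_motif"}.
#' @export
relax <- function(motif, token_index) {
  stopifnot(inherits(motif, "hnox_motif"))
  tk <- motif$tokens
  if (!is.numeric(token_index) || length(token_index) != 1L ||
      is.na(token_index) || token_index < 1L || token_index > nrow(tk))
    stop("'token_index' out of range (motif has ", nrow(tk), " tokens)")
  token_index <- as.integer(token_index)
  if (tk$kind[token_index] != "FIXED")
    stop("token ", token_index, " is a gap, not a fixed residue")
  if (token_index == 1L || token_index == nrow(tk))
    stop("token ", token_index, " is an anchor; anchors cannot be relaxed")
  tk$kind[token_index] <- "GAP"
  tk$residue[token_index] <- NA_character_
  tk$min[token_index] <- 1L
  tk$max[token_index] <- 1L
  tk <- merge_adjacent_gaps(tk)
  m <- new_motif(tk)
  m$source_text <- format_motif(m)
  m
}

#' Index of the first interior fixed token carrying a residue letter
#'
#' Convenience lookup used when relaxing by residue name (e.g. drop the
#' proline).
#'
#' @param motif An \code{"hnox_motif"} object.
#' @param residue One-letter code.
#' @return Token index, or an error if no interior fixed token carries it.
#' @export
fixed_token_index <- function(motif, residue) {
  stopifnot(inherits(motif, "hnox_motif"))
  residue <- toupper(residue)
  tk <- motif$tokens
  idx <- which(tk$kind == "FIXED" & tk$residue == residue)
  idx <- setdiff(idx, c(1L, nrow(tk)))
  if (length(idx) == 0L)
    stop("no interior fixed token with residue ", sQuote(residue))
  idx[1L]
}

# Does `motif` match the character vector `chars` in full (consuming all of
# it)? Recursive over tokens; used by language_contains() and the alignment
# builder's self-checks, not by the scanner.
matches_exactly <- function(motif, string) {
  stopifnot(inherits(motif, "hnox_motif"))
  chars <- strsplit(toupper(string), "")[[1]]
  tk <- motif$tokens
  rec <- function(ti, pos) {
    if (ti > nrow(tk)) return(pos == length(chars) + 1L)
    if (tk$kind[ti] == "FIXED") {
      pos <= length(chars) && chars[pos] == tk$residue[ti] &&
        rec(ti + 1L, pos + 1L)
    } else {
      for (g in tk$min[ti]:tk$max[ti])
        if (pos + g <= length(chars) + 1L && rec(ti + 1L, pos + g))
          return(TRUE)
      FALSE
    }
  }
  rec(1L, 1L)
}

#' Exhaustively test language containment between two motifs
#'
#' Checks, by enumerating every string fully matched by \code{inner} over the
#' given alphabet (up to \code{max_len} residues), that each such string is
#' also fully matched by \code{outer}. This is the oracle backing the
#' relaxation-monotonicity property: relaxing a motif can only grow its
#' language.
#'
#' @param outer,inner \code{"hnox_motif"} objects.
#' @param alphabet Character vector of residue letters used to fill gap
#'   positions.
#' @param max_len Maximum string length to enumerate.
#' @param budget Maximum number of strings to enumerate before refusing.
#' @return \code{TRUE} or \code{FALSE}. If the enumeration would exceed
#'   \code{budget} strings an error is thrown rather than silently
#'   truncating.
#' @export
language_contains <- function(outer, inner, alphabet, max_len,
                              budget = 2e5) {
  stopifnot(inherits(outer, "hnox_motif"), inherits(inner, "hnox_motif"))
  alphabet <- toupper(alphabet)
  tk <- inner$tokens
  gi <- which(tk$kind == "GAP")
  gap_grid <- gap_length_grid(tk)
  # cost: one string per gap vector per assignment of letters to gap slots
  n_strings <- 0
  for (r in seq_len(nrow(gap_grid))) {
    g <- as.integer(gap_grid[r, ])
    len <- sum(tk$kind == "FIXED") + sum(g)
    if (len > max_len) next
    n_strings <- n_strings + length(alphabet)^sum(g)
  }
  if (n_strings > budget)
    stop("language enumeration would generate ", format(n_strings),
         " strings (budget ", format(budget), "); refusing")
  for (r in seq_len(nrow(gap_grid))) {
    g <- as.integer(gap_grid[r, ])
    len <- sum(tk$kind == "FIXED") + sum(g)
    if (len > max_len) next
    total_gap <- sum(g)
    fills <- if (total_gap == 0L) matrix("", 1L, 0L) else
      as.matrix(expand.grid(rep(list(alphabet), total_gap),
                            stringsAsFactors = FALSE))
    for (f in seq_len(nrow(fills))) {
      s <- realize_motif(tk, g, fills[f, ])
      if (!matches_exactly(outer, s)) return(FALSE)
    }
  }
  TRUE
}

# All gap-length combinations of a token table, one row per combination
# (columns follow gap-token order). A single zero-column row when there are
# no gaps.
gap_length_grid <- function(tk, budget = 1e6) {
  gi <- which(tk$kind == "GAP")
  if (length(gi) == 0L) return(matrix(integer(), 1L, 0L))
  n <- prod(tk$max[gi] - tk$min[gi] + 1)
  if (n > budget)
    stop("motif has ", format(n), " gap-length combinations; refusing")
  g <- as.matrix(expand.grid(lapply(gi, function(i) tk$min[i]:tk$max[i])))
  colnames(g) <- NULL
  # lexicographic order of gap vectors
  g[do.call(order, as.data.frame(g)), , drop = FALSE]
}

# Build one concrete realization string: gap lengths `g` (per gap token),
# gap letters `fill` (recycled if too short, default "A").
realize_motif <- function(tk, g, fill = "A") {
  if (length(fill) == 0L) fill <- "A"
  out <- character(0)
  gi <- 0L
  fi <- 0L
  for (i in seq_len(nrow(tk))) {
    if (tk$kind[i] == "FIXED") {
      out <- c(out, tk$residue[i])
    } else {
      gi <- gi + 1L
      if (g[gi] > 0L) {
        idx <- (fi + seq_len(g[gi]) - 1L) %% length(fill) + 1L
        out <- c(out, fill[idx])
        fi <- fi + g[gi]
      }
    }
  }
  paste(out, collapse = "")
}

#' Serialize a motif to or from a JSON token list
#'
#' @param motif An \code{"hnox_motif"} object.
#' @param json JSON text as produced by \code{motif_to_json}.
#' @return \code{motif_to_json}: a JSON string (array of
#'   \code{{kind, residue, min, max}} objects). \code{motif_from_json}: an
#'   \code{"hnox_motif"}.
#' @export
motif_to_json <- function(motif) {
  stopifnot(inherits(motif, "hnox_motif"))
  jsonlite::toJSON(motif$tokens, dataframe = "rows", na = "null")
}

#' @rdname motif_to_json
#' @export
motif_from_json <- function(json) {
  tk <- jsonlite::fromJSON(json)
  tk <- motif_tokens(tk$kind, as.character(tk$residue), tk$min, tk$max)
  if (any(tk$kind == "GAP" & (is.na(tk$min) | tk$min < 1L | tk$max < tk$min)))
    stop("invalid gap bounds in JSON token list")
  if (tk$kind[1L] == "GAP" || tk$kind[nrow(tk)] == "GAP")
    stop("JSON token list is not anchored by fixed residues")
  new_motif(merge_adjacent_gaps(tk))
}

as_motif <- function(x) {
  if (inherits(x, "hnox_motif")) x else parse_motif(x)
}
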