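#' Construct a functional-center alignment
#'
#' Bundles aligned sequences (rows of equal width, \code{"-"} for alignment
#' gaps) with the 1-based column indices of the critical residues — the
#' functionally annotated positions (e.g. the heme-pocket H, P and YxSxR of
#' H-NOX centers) that will become the fixed tokens of an extracted motif.
#' Critical columns are a user annotation, not inferred by conservation
#' scoring.
#'
#' @param rows Named character vector (names are row IDs) or a data frame
#'   with \code{row_id} and \code{aligned} columns.
#' @param critical_columns Integer vector of 1-based column indices.
#' @return An object of class \code{"hnox_alignment"}.
#' @export
center_alignment <- function(rows, critical_columns) {
  if (is.character(rows)) {
    ids <- if (!is.null(names(rows))) names(rows)
           else paste0("row", seq_along(rows))
    rows <- data.frame(row_id = ids, aligned = toupper(unname(rows)),
                       stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(rows), all(c("row_id", "aligned") %in% names(rows)))
  rows$aligned <- toupper(rows$aligned)
  critical_columns <- sort(unique(as.integer(critical_columns)))
  if (length(critical_columns) == 0L)
    stop("at least one critical column is required")
  structure(list(rows = rows, critical_columns = critical_columns),
            class = "hnox_alignment")
}

#' Read an aligned FASTA into a center alignment
#'
#' @param path Aligned FASTA file (all records the same width).
#' @param critical_columns 1-based column indices of the critical residues.
#' @return An \code{"hnox_alignment"}.
#' @export
read_alignment <- function(path, critical_columns) {
  aa <- suppressWarnings(Biostrings::readAAStringSet(path))
  if (length(aa) == 0L) stop("no records in alignment ", path)
  center_alignment(stats::setNames(as.character(aa),
                                   sub("\\s.*$", "", names(aa))),
                   critical_columns)
}

#' Validate a center alignment
#'
#' Collects every violation of the preconditions of [build_motif()]:
#' unequal row widths, empty rows, critical columns out of range, alignment
#' gaps or non-unanimous residues at critical columns, zero-width stretches
#' between consecutive critical columns, and residues outside the span of
#' the critical columns (which the motif would not describe).
#'
#' @param alignment An \code{"hnox_alignment"}.
#' @return A data frame with columns \code{type} and \code{detail}; zero
#'   rows if and only if [build_motif()] will accept the alignment.
#' @export
validate_alignment <- function(alignment) {
  stopifnot(inherits(alignment, "hnox_alignment"))
  issues <- data.frame(type = character(), detail = character(),
                       stringsAsFactors = FALSE)
  add <- function(type, detail)
    rbind(issues, data.frame(type = type, detail = detail,
                             stringsAsFactors = FALSE))
  rows <- alignment$rows
  cc <- alignment$critical_columns
  widths <- nchar(rows$aligned)
  if (any(widths == 0L))
    issues <- add("empty_row", paste(rows$row_id[widths == 0L], collapse = ","))
  if (length(unique(widths)) > 1L) {
    issues <- add("length_mismatch",
                  paste0("row widths ", paste(unique(widths), collapse = "/")))
    return(issues)
  }
  w <- widths[1L]
  if (any(cc < 1L | cc > w)) {
    issues <- add("critical_out_of_range",
                  paste(cc[cc < 1L | cc > w], collapse = ","))
    return(issues)
  }
  mat <- do.call(rbind, strsplit(rows$aligned, ""))
  for (col in cc) {
    res <- mat[, col]
    if (any(res == "-"))
      issues <- add("gap_in_critical", paste0("column ", col))
    res <- unique(res[res != "-"])
    if (length(res) > 1L)
      issues <- add("non_unanimous_critical",
                    paste0("column ", col, ": {",
                           paste(sort(res), collapse = ","), "}"))
  }
  if (length(cc) > 1L) {
    for (k in seq_len(length(cc) - 1L)) {
      lo <- cc[k] + 1L
      hi <- cc[k + 1L] - 1L
      if (hi < lo) next
      counts <- rowSums(mat[, lo:hi, drop = FALSE] != "-")
      if (any(counts == 0L))
        issues <- add("empty_gap_stretch",
                      paste0("between columns ", cc[k], " and ", cc[k + 1L],
                             " in row(s) ",
                             paste(rows$row_id[counts == 0L], collapse = ",")))
    }
  }
  outside <- setdiff(seq_len(w), seq(min(cc), max(cc)))
  if (length(outside) && any(mat[, outside, drop = FALSE] != "-"))
    issues <- add("residue_outside_critical_span",
                  "non-gap characters outside the outermost critical columns")
  issues
}

#' Extract a flexible-gap motif from a center alignment
#'
#' Reproduces consensus-motif extraction from an alignment of functional
#' centers: each critical column (which must carry a single unanimous
#' residue with no alignment gap) becomes a fixed token, and each stretch
#' between consecutive critical columns becomes a gap token whose bounds are
#' the minimum and maximum, over rows, of the number of residues (non-gap
#' characters) in that stretch. The result is canonical, so an alignment
#' whose stretch counts span 12, 14-16, 1 and 1 around unanimous H, P, Y, S,
#' R columns yields \code{"Hx(12)Px(14,16)YxSxR"}.
#'
#' @param alignment An \code{"hnox_alignment"} (see [center_alignment()]).
#' @return An \code{"hnox_motif"}.
#' @export
build_motif <- function(alignment) {
  issues <- validate_alignment(alignment)
  if (nrow(issues))
    stop("invalid center alignment:\n  ",
         paste(paste0(issues$type, ": ", issues$detail), collapse = "\n  "))
  rows <- alignment$rows
  cc <- alignment$critical_columns
  mat <- do.call(rbind, strsplit(rows$aligned, ""))
  toks <- motif_tokens()
  for (k in seq_along(cc)) {
    toks <- rbind(toks, motif_tokens("FIXED", mat[1L, cc[k]], 1L, 1L))
    if (k < length(cc)) {
      lo <- cc[k] + 1L
      hi <- cc[k + 1L] - 1L
      if (hi >= lo) {
        counts <- rowSums(mat[, lo:hi, drop = FALSE] != "-")
        toks <- rbind(toks, motif_tokens("GAP", NA_character_,
                                         min(counts), max(counts)))
      }
    }
  }
  m <- new_motif(merge_adjacent_gaps(toks))
  m$source_text <- format_motif(m)
  m
}

#' @export
print.hnox_alignment <- function(x, ...) {
  cat("Center alignment: ", nrow(x$rows), " rows x ",
      nchar(x$rows$aligned[1L]), " columns; critical columns ",
      paste(x$critical_columns, collapse = ","), "\n", sep = "")
  invisible(x)
}
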