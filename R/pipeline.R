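#' Validate a discovery/validation run configuration
#'
#' A run configuration is a plain list (or a path to a JSON document) with
#' the fields:
#' \describe{
#'   \item{motif}{motif string, \emph{or}}
#'   \item{alignment, critical_columns}{aligned FASTA path plus critical
#'     column indices (exactly one motif source must be given);}
#'   \item{relax_residue / relax_index}{optional: interior fixed residue
#'     letter (first occurrence) or token index to relax;}
#'   \item{fasta}{proteome FASTA path (discovery);}
#'   \item{policy}{match policy (default ALL_REALIZATIONS);}
#'   \item{spectra_manifest}{spectra manifest JSON path (validation,
#'     optional for discovery);}
#'   \item{out_dir}{output directory;}
#'   \item{classification}{optional overrides: \code{min_prominence},
#'     \code{titration_tolerance}.}
#' }
#' All referenced paths are checked before any stage runs.
#'
#' @param config List or path to a JSON config.
#' @return The normalized config list, invisibly on error-free validation.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  has_motif <- !is.null(config$motif)
  has_aln <- !is.null(config$alignment)
  if (has_motif && has_aln)
    stop("config must provide exactly one motif source: ",
         "'motif' or 'alignment' + 'critical_columns'")
  if (!has_motif && !has_aln && !is.null(config$fasta))
    stop("scanning requires a motif source: ",
         "'motif' or 'alignment' + 'critical_columns'")
  if (has_aln && is.null(config$critical_columns))
    stop("'alignment' requires 'critical_columns'")
  if (is.null(config$out_dir)) stop("config requires 'out_dir'")
  for (f in c("alignment", "fasta", "spectra_manifest"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config path does not exist: ", f, " = ", config[[f]])
  if (is.null(config$policy)) config$policy <- "ALL_REALIZATIONS"
  invisible(config)
}

config_motifs <- function(config) {
  strict <- if (!is.null(config$motif)) parse_motif(config$motif)
            else build_motif(read_alignment(config$alignment,
                                            config$critical_columns))
  relaxed <- NULL
  if (!is.null(config$relax_index))
    relaxed <- relax(strict, as.integer(config$relax_index))
  else if (!is.null(config$relax_residue))
    relaxed <- relax(strict, fixed_token_index(strict, config$relax_residue))
  list(strict = strict, relaxed = relaxed)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the motif-discovery workflow
#'
#' Ties the pipeline together the way the original search was run: obtain a
#' motif (parsed or extracted from a center alignment), optionally relax it
#' by dropping an interior fixed residue, scan a proteome with the strict
#' and relaxed motifs, and write match tables, locus-level candidate
#' tables, per-match key-residue maps and a JSON run report. The workflow
#' contains no randomness; identical configs produce identical outputs.
#'
#' @param config Run configuration (list or JSON path), see
#'   [validate_config()]. Requires \code{fasta}.
#' @return The run report (list of class \code{"hnox_report"}), invisibly.
#'   Files written to \code{out_dir}: \code{motifs.txt},
#'   \code{matches_strict.tsv} / \code{matches_relaxed.tsv},
#'   \code{candidates_strict.tsv} / \code{candidates_relaxed.tsv} and
#'   \code{report.json}.
#' @export
run_discovery <- function(config) {
  config <- validate_config(config)
  if (is.null(config$fasta)) stop("discovery requires a 'fasta' path")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  motifs <- config_motifs(config)
  records <- read_fasta(config$fasta)

  report <- list(tool = "hnoxscout", version = as.character(utils::packageVersion("hnoxscout")),
                 r_version = R.version.string,
                 policy = config$policy, n_records = nrow(records),
                 motifs = list(), stages = character())
  motif_lines <- character()
  for (nm in c("strict", "relaxed")) {
    m <- motifs[[nm]]
    if (is.null(m)) next
    ms <- scan_proteome(m, records, config$policy)
    tab <- match_table(ms)
    cand <- collapse_to_loci(ms)
    write_tsv(tab, file.path(config$out_dir, paste0("matches_", nm, ".tsv")))
    write_tsv(as.data.frame(cand),
              file.path(config$out_dir, paste0("candidates_", nm, ".tsv")))
    report$motifs[[nm]] <- list(
      motif = format_motif(m),
      n_matching_records = ms$n_matching_records,
      n_realizations = ms$n_realizations,
      n_loci = nrow(cand))
    motif_lines <- c(motif_lines, paste0(nm, "\t", format_motif(m)))
    report$stages <- c(report$stages, paste0("scan_", nm))
  }
  writeLines(motif_lines, file.path(config$out_dir, "motifs.txt"))

  if (!is.null(config$spectra_manifest)) {
    report$validation <- run_validation(config)
    report$stages <- c(report$stages, "validation")
  } else {
    report$stages <- c(report$stages, "spectra_skipped")
  }
  report$coordinate_convention <- "1-based inclusive residue positions"
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  class(report) <- "hnox_report"
  invisible(report)
}

#' @export
print.hnox_report <- function(x, ...) {
  cat("hnoxscout run (", paste(x$stages, collapse = ", "), ")\n", sep = "")
  for (nm in names(x$motifs))
    cat("  ", nm, " ", x$motifs[[nm]]$motif, ": ",
        x$motifs[[nm]]$n_matching_records, " matching records, ",
        x$motifs[[nm]]$n_loci, " loci\n", sep = "")
  invisible(x)
}

read_manifest <- function(path) {
  man <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  base <- dirname(path)
  resolve <- function(f) if (file.exists(f)) f else file.path(base, f)
  bad <- character()
  if (!is.null(man$spectra)) {
    for (i in seq_along(man$spectra)) {
      man$spectra[[i]]$file <- resolve(man$spectra[[i]]$file)
      if (!file.exists(man$spectra[[i]]$file))
        bad <- c(bad, man$spectra[[i]]$file)
    }
  }
  for (sec in c("titration", "dissociation")) {
    if (is.null(man[[sec]])) next
    man[[sec]]$files <- vapply(man[[sec]]$files, resolve, character(1))
    bad <- c(bad, man[[sec]]$files[!file.exists(man[[sec]]$files)])
  }
  if (length(bad))
    stop("manifest references missing file(s): ", paste(bad, collapse = ", "))
  if (is.null(man$spectra) && is.null(man$titration) &&
      is.null(man$dissociation))
    stop("manifest lists no spectra, titration or dissociation section")
  man
}

#' Run the spectral-validation workflow
#'
#' Reads a spectra manifest (JSON listing spectrum CSV/TSV files, an
#' optional titration section with donor concentrations and an optional
#' dissociation section with time points), classifies each spectrum into a
#' heme state, analyzes titration saturation and dissociation recovery, and
#' writes \code{states.tsv} plus \code{validation.json} to \code{out_dir}.
#'
#' Manifest shape:
#' \preformatted{
#' {"spectra": [{"file": "ferric.csv", "label": "oxidized"}, ...],
#'  "titration": {"files": [...], "concentrations_uM": [...],
#'                "tolerance_AU": 0.005},
#'  "dissociation": {"files": [...], "times_h": [...]}}
#' }
#' File paths are resolved relative to the manifest.
#'
#' @param config Run configuration with \code{spectra_manifest} and
#'   \code{out_dir} set (motif source fields are not needed when called
#'   directly, but tolerated).
#' @return List with \code{states} (data frame), \code{titration}
#'   (\code{"hnox_saturation"} or NULL) and \code{dissociation} (list or
#'   NULL), invisibly.
#' @export
run_validation <- function(config) {
  config <- validate_config(config)
  if (is.null(config$spectra_manifest))
    stop("validation requires a 'spectra_manifest' path")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- read_manifest(config$spectra_manifest)
  min_prom <- config$classification$min_prominence
  if (is.null(min_prom)) min_prom <- 0.02
  out <- list(states = NULL, titration = NULL, dissociation = NULL)

  if (!is.null(man$spectra)) {
    rows <- lapply(man$spectra, function(e) {
      sp <- read_spectrum(e$file, if (!is.null(e$label)) e$label
                          else basename(e$file))
      st <- classify_spectrum(sp, min_prominence = min_prom)
      data.frame(label = sp$label, file = basename(e$file),
                 state = st$state, rationale = st$rationale,
                 stringsAsFactors = FALSE)
    })
    out$states <- do.call(rbind, rows)
    write_tsv(out$states, file.path(config$out_dir, "states.tsv"))
  }
  if (!is.null(man$titration)) {
    tol <- man$titration$tolerance_AU
    if (is.null(tol)) tol <- config$classification$titration_tolerance
    if (is.null(tol)) tol <- 0.005
    series <- titration_series(
      unlist(man$titration$concentrations_uM),
      lapply(man$titration$files, read_spectrum))
    out$titration <- analyze_titration(series, tolerance = tol)
  }
  if (!is.null(man$dissociation)) {
    series <- dissociation_series(
      unlist(man$dissociation$times_h),
      lapply(man$dissociation$files, read_spectrum))
    out$dissociation <- analyze_dissociation(series,
                                             min_prominence = min_prom)
  }
  json <- list(
    states = out$states,
    titration = if (!is.null(out$titration)) unclass(out$titration),
    dissociation = out$dissociation)
  jsonlite::write_json(json, file.path(config$out_dir, "validation.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(out)
}
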