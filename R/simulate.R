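#' Built-in heme spectral-state templates
#'
#' Band inventories (Gaussian center/width/height) for the five reference
#' states: ferric His-ligated heme (Soret 408 nm plus a broad 530 nm
#' absorption), dithionite-reduced 6-coordinate ferrous heme (Soret 418 nm
#' with beta/alpha bands at 525/553 nm), the 5-coordinate nitrosyl complex
#' (broad Soret at 398 nm), free hemin (Soret 436 nm with a broad shoulder
#' around 400 nm) and the heme-free apoprotein (no bands). Band centers are
#' the reference wavelengths the classifier windows are built around; widths
#' and heights are generator choices at realistic Soret/alpha-beta
#' intensity ratios.
#'
#' @param state One of \code{"ferric"}, \code{"ferrous"}, \code{"no_5c"},
#'   \code{"hemin"}, \code{"apo"}.
#' @param noise_sd Gaussian noise standard deviation in AU.
#' @param baseline \code{c(intercept, slope_per_nm)} of the linear baseline.
#' @return An object of class \code{"hnox_template"}: list with
#'   \code{state}, \code{bands} (data frame \code{center}, \code{width},
#'   \code{height}), \code{baseline} and \code{noise_sd}.
#' @export
spectrum_template <- function(state = c("ferric", "ferrous", "no_5c",
                                        "hemin", "apo"),
                              noise_sd = 0,
                              baseline = c(0.03, -2e-5)) {
  state <- match.arg(state)
  bands <- switch(state,
    ferric = data.frame(center = c(408, 530), width = c(12, 22),
                        height = c(0.50, 0.06)),
    ferrous = data.frame(center = c(418, 525, 553), width = c(10, 7, 7),
                         height = c(0.55, 0.055, 0.065)),
    no_5c = data.frame(center = 398, width = 13, height = 0.42),
    hemin = data.frame(center = c(436, 400), width = c(13, 20),
                       height = c(0.35, 0.15)),
    apo = data.frame(center = numeric(), width = numeric(),
                     height = numeric()))
  structure(list(state = state, bands = bands,
                 baseline = as.numeric(baseline), noise_sd = noise_sd),
            class = "hnox_template")
}

template_state_call <- function(state) {
  switch(state,
         ferric = "FERRIC_HIS_LIGATED", ferrous = "FERROUS_6C",
         no_5c = "FERROUS_5C_NO", hemin = "FREE_HEMIN",
         apo = "APO_NO_HEME")
}

template_values <- function(template, grid) {
  v <- template$baseline[1L] + template$baseline[2L] * (grid - 350)
  b <- template$bands
  for (k in seq_len(nrow(b)))
    v <- v + b$height[k] * exp(-(grid - b$center[k])^2 / (2 * b$width[k]^2))
  v
}

#' Generate a synthetic UV/Vis spectrum from a state template
#'
#' Sum of Gaussian bands plus a linear baseline plus seeded Gaussian noise.
#' Identical template, grid and seed give byte-identical output.
#'
#' @param template An \code{"hnox_template"} from [spectrum_template()].
#' @param grid Wavelength grid in nm; must cover every band center.
#' @param seed Integer RNG seed (required when \code{noise_sd > 0}).
#' @return An \code{"hnox_spectrum"} labelled with the template state.
#' @export
gen_spectrum <- function(template, grid = seq(350, 600, by = 1),
                         seed = NULL) {
  stopifnot(inherits(template, "hnox_template"))
  b <- template$bands
  if (nrow(b) && (min(grid) > min(b$center) || max(grid) < max(b$center)))
    stop("grid does not cover all band centers (",
         paste(b$center, collapse = ", "), " nm)")
  v <- template_values(template, grid)
  if (template$noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    set.seed(as.integer(seed))
    v <- v + stats::rnorm(length(grid), sd = template$noise_sd)
  }
  spectrum(grid, v, template$state)
}

uniform_freqs <- function() {
  stats::setNames(rep(1 / 20, 20L), AA_STANDARD)
}

check_freqs <- function(freqs) {
  if (is.null(freqs)) return(uniform_freqs())
  stopifnot(!is.null(names(freqs)), all(names(freqs) %in% AA_STANDARD),
            all(freqs >= 0), sum(freqs) > 0)
  full <- stats::setNames(numeric(20L), AA_STANDARD)
  full[names(freqs)] <- freqs
  full / sum(full)
}

random_chain <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

#' Generate a proteome with planted motif instances
#'
#' Background sequences are i.i.d. draws from \code{freqs} (uniform over the
#' 20 standard residues by default). Each plant samples a gap-length vector
#' uniformly from the motif's bounds, picks a start uniformly, and writes
#' the fixed residues over the background. In \code{exclusive} mode a record
#' is re-rolled until scanning it with \code{exclusive_motif} returns
#' exactly the planted spans (and any motif in \code{forbid_motifs} returns
#' nothing), so the recorded truth is the complete ground truth. Records
#' carry AGI-style gene-model identifiers; with probability
#' \code{isoform_dup} a planted record gains a \code{".2"} isoform that
#' shares the planted region (the duplicate is truncated shortly after the
#' planted span, as gene models often differ at their ends).
#'
#' @param n_records Number of base records.
#' @param seq_length Residue length of each background sequence (scalar or
#'   per-record vector).
#' @param motif Motif to plant (\code{"hnox_motif"} or string); may be NULL
#'   when \code{n_plants = 0}.
#' @param n_plants Number of planted instances (at most one per record).
#' @param freqs Named background residue frequencies (subset of the 20
#'   standard letters; renormalized).
#' @param isoform_dup Probability that a planted record gains a duplicate
#'   gene model.
#' @param exclusive Logical; re-roll records until ground truth is exact.
#' @param seed Integer RNG seed (required).
#' @param exclusive_motif Motif used for the exclusivity scan (defaults to
#'   \code{motif}); pass a more permissive motif to guarantee cleanliness
#'   with respect to it.
#' @param forbid_motifs List of motifs that must not match anywhere.
#' @param max_reroll Re-roll budget per record before giving up.
#' @return An object of class \code{"hnox_proteome"}: list with
#'   \code{records} (data frame as from [read_fasta()]), \code{truth}
#'   (data frame \code{seq_id}, \code{start}, \code{end}, \code{gaps},
#'   \code{motif}) and \code{params}.
#' @export
gen_proteome <- function(n_records, seq_length, motif = NULL, n_plants = 0L,
                         freqs = NULL, isoform_dup = 0, exclusive = TRUE,
                         seed, exclusive_motif = motif,
                         forbid_motifs = list(), max_reroll = 200L) {
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  freqs <- check_freqs(freqs)
  n_records <- as.integer(n_records)
  seq_length <- rep_len(as.integer(seq_length), n_records)
  n_plants <- as.integer(n_plants)
  if (n_plants > 0L) {
    motif <- as_motif(motif)
    if (is.null(exclusive_motif)) exclusive_motif <- motif
    exclusive_motif <- as_motif(exclusive_motif)
    if (n_plants > n_records)
      stop("at most one plant per record: n_plants > n_records")
    if (any(seq_length[seq_len(n_plants)] < span_bounds(motif)[["max_span"]]))
      stop("planted span may exceed sequence length; increase seq_length")
  }
  forbid_motifs <- lapply(forbid_motifs, as_motif)
  planted_rec <- if (n_plants > 0L) sort(sample.int(n_records, n_plants))
                 else integer()

  ids <- sprintf("At%dg%05d.1", (seq_len(n_records) - 1L) %% 5L + 1L,
                 seq_len(n_records) * 10L)
  records <- data.frame(seq_id = character(), description = character(),
                        sequence = character(), stringsAsFactors = FALSE)
  truth <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), gaps = character(),
                      motif = character(), stringsAsFactors = FALSE)

  for (i in seq_len(n_records)) {
    has_plant <- i %in% planted_rec
    for (attempt in seq_len(max_reroll)) {
      chars <- random_chain(seq_length[i], freqs)
      plant <- NULL
      if (has_plant) {
        tk <- motif$tokens
        gi <- which(tk$kind == "GAP")
        g <- if (length(gi))
          vapply(gi, function(k) {
            if (tk$min[k] == tk$max[k]) tk$min[k]
            else sample(tk$min[k]:tk$max[k], 1L)
          }, integer(1)) else integer()
        lens <- ifelse(tk$kind == "FIXED", 1L, 0L)
        lens[gi] <- g
        total <- sum(lens)
        start <- sample.int(seq_length[i] - total + 1L, 1L)
        fixed_idx <- which(tk$kind == "FIXED")
        pos <- start + cumsum(c(0L, lens[-length(lens)]))[fixed_idx]
        chars[pos] <- tk$residue[fixed_idx]
        plant <- data.frame(seq_id = ids[i], start = start,
                            end = start + total - 1L,
                            gaps = paste(g, collapse = ","),
                            motif = format_motif(motif),
                            stringsAsFactors = FALSE)
      }
      rec <- data.frame(seq_id = ids[i], description = "synthetic",
                        sequence = paste(chars, collapse = ""),
                        stringsAsFactors = FALSE)
      if (!exclusive || record_is_clean(rec, plant, exclusive_motif,
                                        forbid_motifs, has_plant))
        break
      if (attempt == max_reroll)
        stop("could not generate a clean record within ", max_reroll,
             " re-rolls (record ", ids[i], ")")
    }
    records <- rbind(records, rec)
    if (!is.null(plant)) truth <- rbind(truth, plant)
    if (has_plant && isoform_dup > 0 && stats::runif(1L) < isoform_dup) {
      iso_id <- sub("\\.1$", ".2", ids[i])
      cut <- min(seq_length[i], plant$end + 20L)
      iso <- data.frame(seq_id = iso_id, description = "synthetic isoform",
                        sequence = substr(rec$sequence, 1L, cut),
                        stringsAsFactors = FALSE)
      records <- rbind(records, iso)
      truth <- rbind(truth, transform(plant, seq_id = iso_id))
    }
  }
  structure(list(records = structure(records,
                                     class = c("hnox_records", "data.frame")),
                 truth = truth,
                 params = list(n_records = n_records, seq_length = seq_length,
                               n_plants = n_plants, freqs = freqs,
                               isoform_dup = isoform_dup,
                               exclusive = exclusive, seed = seed)),
            class = "hnox_proteome")
}

record_is_clean <- function(rec, plant, exclusive_motif, forbid_motifs,
                            has_plant) {
  if (has_plant || !is.null(exclusive_motif)) {
    if (is.null(exclusive_motif)) return(TRUE)
    hits <- find_matches(exclusive_motif, rec)
    want <- if (is.null(plant)) character()
            else paste(plant$start, plant$end)
    got <- unique(paste(hits$start, hits$end))
    if (!setequal(got, want)) return(FALSE)
  }
  for (fm in forbid_motifs)
    if (nrow(find_matches(fm, rec)) > 0L) return(FALSE)
  TRUE
}

#' @export
print.hnox_proteome <- function(x, ...) {
  cat("Synthetic proteome: ", nrow(x$records), " records, ",
      nrow(x$truth), " planted instance(s), seed ", x$params$seed,
      "\n", sep = "")
  invisible(x)
}

#' Expected number of motif realizations on a random sequence
#'
#' Closed-form expectation under an i.i.d. background: summing over every
#' gap-length vector \eqn{g}, the number of admissible anchor positions
#' \eqn{(L - span(g) + 1)^+} times the probability that all fixed residues
#' agree, \eqn{\prod_k f(r_k)}. Serves as the analytic oracle for scanner
#' calibration against Monte Carlo counts.
#'
#' @param motif An \code{"hnox_motif"} (or motif string).
#' @param seq_length Sequence length L in residues.
#' @param freqs Named residue frequencies (uniform default).
#' @return Expected realization count (numeric).
#' @export
expected_random_hits <- function(motif, seq_length, freqs = NULL) {
  motif <- as_motif(motif)
  freqs <- check_freqs(freqs)
  tk <- motif$tokens
  p_fixed <- prod(freqs[tk$residue[tk$kind == "FIXED"]])
  grid <- gap_length_grid(tk)
  n_fixed <- sum(tk$kind == "FIXED")
  spans <- if (ncol(grid) == 0L) n_fixed else rowSums(grid) + n_fixed
  sum(pmax(seq_length - spans + 1, 0)) * p_fixed
}

#' Generate an NO-titration series from a binding isotherm
#'
#' At donor concentration \eqn{c} the bound fraction is
#' \eqn{f = c / (K_{app} + c)}; each step's spectrum is the corresponding
#' mixture of the clean 6c-ferrous and 5c-nitrosyl template spectra, plus
#' seeded Gaussian noise.
#'
#' @param K_app Apparent affinity constant in uM (> 0).
#' @param concentrations Non-decreasing donor concentrations (uM).
#' @param seed Integer RNG seed.
#' @param noise_sd Per-point Gaussian noise in AU.
#' @param grid Wavelength grid (nm).
#' @param start_template,end_template State templates mixed along the
#'   titration (defaults: ferrous to 5c-NO).
#' @return An \code{"hnox_titration"} with an extra \code{fraction_bound}
#'   element recording the generating isotherm.
#' @export
gen_titration <- function(K_app, concentrations, seed, noise_sd = 0,
                          grid = seq(350, 600, by = 1),
                          start_template = spectrum_template("ferrous"),
                          end_template = spectrum_template("no_5c")) {
  if (K_app <= 0) stop("'K_app' must be positive")
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  f <- concentrations / (K_app + concentrations)
  v0 <- template_values(start_template, grid)
  v1 <- template_values(end_template, grid)
  spectra <- lapply(seq_along(f), function(i) {
    v <- (1 - f[i]) * v0 + f[i] * v1
    if (noise_sd > 0) v <- v + stats::rnorm(length(grid), sd = noise_sd)
    spectrum(grid, v, sprintf("%g uM donor", concentrations[i]))
  })
  out <- titration_series(concentrations, spectra)
  out$fraction_bound <- f
  out$K_app <- K_app
  out
}

#' Generate a post-NO-saturation dissociation time series
#'
#' The ferric fraction recovers as \eqn{1 - e^{-k t}}; spectra mix the
#' clean 5c-nitrosyl and ferric template spectra accordingly, plus seeded
#' noise. Emulates the slow reappearance of the 408 nm Soret peak as NO is
#' released.
#'
#' @param rate_k First-order recovery rate (per hour, > 0).
#' @param times Strictly ascending time points (hours).
#' @param seed Integer RNG seed.
#' @param noise_sd Per-point Gaussian noise in AU.
#' @param grid Wavelength grid (nm).
#' @return An \code{"hnox_timeseries"} with an extra \code{fraction_ferric}
#'   element.
#' @export
gen_dissociation <- function(rate_k, times, seed, noise_sd = 0,
                             grid = seq(350, 600, by = 1)) {
  if (rate_k <= 0) stop("'rate_k' must be positive")
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  frac <- 1 - exp(-rate_k * times)
  v0 <- template_values(spectrum_template("no_5c"), grid)
  v1 <- template_values(spectrum_template("ferric"), grid)
  spectra <- lapply(seq_along(times), function(i) {
    v <- (1 - frac[i]) * v0 + frac[i] * v1
    if (noise_sd > 0) v <- v + stats::rnorm(length(grid), sd = noise_sd)
    spectrum(grid, v, sprintf("t = %g h", times[i]))
  })
  out <- dissociation_series(times, spectra)
  out$fraction_ferric <- frac
  out$rate_k <- rate_k
  out
}
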