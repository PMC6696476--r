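#' Construct a UV/Vis spectrum
#'
#' @param wavelength Strictly ascending wavelength grid in nm.
#' @param absorbance Absorbance values in AU, same length.
#' @param label Free-text label.
#' @return An object of class \code{"hnox_spectrum"}.
#' @export
spectrum <- function(wavelength, absorbance, label = "") {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance))
    stop("wavelength and absorbance differ in length")
  if (length(wavelength) < 2L || any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly ascending")
  if (anyNA(absorbance)) stop("absorbance contains NA")
  structure(list(wavelength = wavelength, absorbance = absorbance,
                 label = label),
            class = "hnox_spectrum")
}

#' @export
print.hnox_spectrum <- function(x, ...) {
  cat("UV/Vis spectrum", if (nzchar(x$label)) paste0(" [", x$label, "]"),
      ": ", length(x$wavelength), " points, ",
      min(x$wavelength), "-", max(x$wavelength), " nm\n", sep = "")
  invisible(x)
}

#' @export
plot.hnox_spectrum <- function(x, ...) {
  plot(x$wavelength, x$absorbance, type = "l",
       xlab = "wavelength (nm)", ylab = "absorbance (AU)",
       main = x$label, ...)
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Reads wavelength/absorbance tables in CSV or TSV form (separator
#' auto-detected), with or without a header line.
#'
#' @param path File path.
#' @param label Label for the spectrum (defaults to the file name).
#' @return An \code{"hnox_spectrum"}.
#' @export
read_spectrum <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- is.na(suppressWarnings(as.numeric(strsplit(first, sep)[[1]][1L])))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected two columns (wavelength, absorbance) in ", path)
  spectrum(df[[1L]], df[[2L]], label)
}

#' Write a spectrum as CSV
#'
#' @param x An \code{"hnox_spectrum"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "hnox_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = x$wavelength,
                              absorbance_AU = x$absorbance),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Smooth a spectrum by moving least-squares polynomial fitting
#'
#' Savitzky-Golay-style smoothing: each point is replaced by the value at
#' its own wavelength of a degree-\code{order} polynomial fitted to the
#' surrounding \code{window} points. Near the ends the window shrinks
#' symmetrically, so the grid is unchanged and no points are discarded.
#' Polynomials of degree at most \code{order} are reproduced exactly.
#'
#' @param x An \code{"hnox_spectrum"}.
#' @param window Odd integer window width in points.
#' @param order Polynomial order, \code{< window}.
#' @return The smoothed \code{"hnox_spectrum"} on the same grid.
#' @export
smooth_spectrum <- function(x, window = 11L, order = 2L) {
  stopifnot(inherits(x, "hnox_spectrum"))
  n <- length(x$wavelength)
  window <- as.integer(window)
  order <- as.integer(order)
  if (window %% 2L == 0L) stop("'window' must be odd")
  if (order >= window) stop("'order' must be smaller than 'window'")
  if (window > n) stop("'window' exceeds the number of points (", n, ")")
  h <- (window - 1L) %/% 2L
  w <- x$wavelength
  a <- x$absorbance
  out <- numeric(n)
  uniform <- h > 0L && diff(range(diff(w))) < 1e-9 * mean(diff(w))
  interior <- (h + 1L):(n - h)
  if (uniform) {
    # fixed design => one projection vector for all interior points
    X <- outer(-h:h, 0:order, "^")
    wt <- solve(crossprod(X), t(X))[1L, ]
    sm <- stats::filter(a, rev(wt), sides = 2L)
    out[interior] <- sm[interior]
  } else {
    for (i in interior) out[i] <- local_polyfit(w, a, i, h, order)
  }
  for (i in seq_len(n)[-interior]) {
    hi <- min(h, i - 1L, n - i)
    out[i] <- if (2L * hi < order + 1L) a[i]
              else local_polyfit(w, a, i, hi, min(order, 2L * hi))
  }
  spectrum(w, out, x$label)
}

local_polyfit <- function(w, a, i, h, order) {
  idx <- (i - h):(i + h)
  X <- outer(w[idx] - w[i], 0:order, "^")
  drop(solve(crossprod(X), crossprod(X, a[idx]))[1L])
}

#' Default heme band-class windows (nm)
#'
#' Soret, beta and alpha search windows used by [detect_peaks()] to label
#' peak calls.
#'
#' @return Named list of \code{c(lo, hi)} windows.
#' @export
band_windows <- function() {
  list(SORET = c(380, 450), BETA = c(515, 535), ALPHA = c(545, 565))
}

#' Detect absorption peaks in a spectrum
#'
#' A linear baseline, estimated over \code{baseline_range} (by default the
#' flat long-wavelength tail at 570-600 nm), is subtracted; local maxima in
#' \code{region} with topographic prominence at least \code{min_prominence}
#' are reported. Peak positions are refined to sub-grid precision by a
#' half-height apex centroid bounded by the peak's prominence cols (so
#' neighbouring bands never leak into the estimate), falling back to
#' 3-point parabolic interpolation for peaks only a few grid points wide.
#' Peaks are labelled SORET / BETA / ALPHA / OTHER according to
#' \code{windows}.
#'
#' @param x An \code{"hnox_spectrum"}.
#' @param min_prominence Minimum prominence in AU.
#' @param region \code{c(lo, hi)} wavelength interval to search (must lie
#'   within the grid).
#' @param windows Band-class windows, see [band_windows()].
#' @param baseline_range \code{c(lo, hi)} interval for the linear baseline
#'   estimate, or \code{NULL} to skip baseline correction. Silently skipped
#'   when the grid does not cover it.
#' @return Data frame of class \code{"hnox_peaks"} with columns
#'   \code{lambda_max} (nm), \code{height} (AU above baseline),
#'   \code{prominence} (AU) and \code{band_class}, sorted by descending
#'   prominence.
#' @export
detect_peaks <- function(x, min_prominence = 0.02,
                         region = range(x$wavelength),
                         windows = band_windows(),
                         baseline_range = c(570, 600)) {
  stopifnot(inherits(x, "hnox_spectrum"))
  w <- x$wavelength
  a <- x$absorbance
  if (length(region) != 2L || region[1L] >= region[2L] ||
      region[1L] < min(w) || region[2L] > max(w))
    stop("'region' must be a non-empty interval within the wavelength grid")
  if (!is.null(baseline_range)) {
    bi <- which(w >= baseline_range[1L] & w <= baseline_range[2L])
    if (length(bi) >= 2L) {
      fit <- stats::lm.fit(cbind(1, w[bi]), a[bi])
      a <- a - drop(cbind(1, w) %*% fit$coefficients)
    }
  }
  n <- length(a)
  cand <- which(diff(c(-Inf, a)) > 0 & diff(c(a, -Inf)) <= 0)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[w[cand] >= region[1L] & w[cand] <= region[2L]]
  if (length(cand) == 0L)
    return(empty_peaks())
  prom <- lapply(cand, function(i) peak_prominence(a, i))
  keep <- vapply(prom, `[[`, numeric(1), "prominence") >= min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0L)
    return(empty_peaks())
  out <- do.call(rbind, lapply(seq_along(cand), function(k) {
    i <- cand[k]
    refined <- refine_apex(w, a, i, prom[[k]]$left, prom[[k]]$right)
    data.frame(lambda_max = refined[["lambda"]],
               height = refined[["height"]],
               prominence = prom[[k]]$prominence,
               band_class = classify_band(refined[["lambda"]], windows),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$prominence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hnox_peaks", "data.frame")
  out
}

empty_peaks <- function() {
  out <- data.frame(lambda_max = numeric(), height = numeric(),
                    prominence = numeric(), band_class = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("hnox_peaks", "data.frame")
  out
}

# Topographic prominence: height above the higher of the two key cols (the
# minima between the peak and the nearest higher ground on each side; the
# data edge counts as higher ground at the minimum to the edge). Also
# returns the col indices, which bound the peak's own territory.
peak_prominence <- function(a, i) {
  left <- a[seq_len(i - 1L)]
  right <- a[(i + 1L):length(a)]
  jl <- if (any(left > a[i])) max(which(left > a[i])):(i - 1L)
        else seq_len(i - 1L)
  col_left_idx <- jl[which.min(left[jl])]
  jr <- if (any(right > a[i])) seq_len(min(which(right > a[i])))
        else seq_along(right)
  col_right_idx <- i + jr[which.min(right[jr])]
  list(prominence = a[i] - max(a[col_left_idx], a[col_right_idx]),
       left = col_left_idx, right = col_right_idx)
}

# Apex refinement: centroid of the symmetric region around the maximum that
# lies above half the apex height, bounded by the peak's prominence cols so
# a neighbouring peak never leaks into the estimate. Exact for symmetric
# band shapes and far less noise-sensitive than a 3-point parabola on broad
# bands; peaks too narrow for a centroid fall back to 3-point parabolic
# interpolation.
refine_apex <- function(w, a, i, lbound, rbound, frac = 0.5) {
  thr <- frac * a[i]
  lo <- i
  while (lo > lbound && lo > 1L && a[lo - 1L] > thr) lo <- lo - 1L
  hi <- i
  while (hi < rbound && hi < length(a) && a[hi + 1L] > thr) hi <- hi + 1L
  if (min(i - lo, hi - i) < 2L) return(parabolic_refine(w, a, i))
  idx <- lo:hi
  lambda <- sum(w[idx] * (a[idx] - thr)) / sum(a[idx] - thr)
  c(lambda = lambda, height = a[i])
}

parabolic_refine <- function(w, a, i) {
  y1 <- a[i - 1L]; y2 <- a[i]; y3 <- a[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < .Machine$double.eps) return(c(lambda = w[i], height = y2))
  d <- 0.5 * (y1 - y3) / denom
  d <- max(-1, min(1, d))
  step <- (w[i + 1L] - w[i - 1L]) / 2
  c(lambda = w[i] + d * step, height = y2 - 0.25 * (y1 - y3) * d)
}

classify_band <- function(lambda, windows) {
  for (nm in names(windows))
    if (lambda >= windows[[nm]][1L] && lambda <= windows[[nm]][2L])
      return(nm)
  "OTHER"
}

#' Default heme-state classification windows (nm)
#'
#' Soret-position windows for each state, plus the beta/alpha windows
#' required for the 6-coordinate ferrous call: ferric His-ligated heme at
#' 408 nm, dithionite-reduced 6c ferrous at 418 nm with beta/alpha bands at
#' 525/553 nm, the 5-coordinate nitrosyl complex at 398 nm and free hemin
#' at 436 nm. Widths default to +/-4 nm around Soret centers (+/-5 for
#' hemin) and +/-6 nm around the alpha/beta bands.
#'
#' @return Named list of \code{c(lo, hi)} windows.
#' @export
heme_state_windows <- function() {
  list(FERRIC_HIS_LIGATED = c(404, 412),
       FERROUS_6C = c(414, 422),
       FERROUS_5C_NO = c(394, 402),
       FREE_HEMIN = c(431, 441),
       BETA_6C = c(519, 531),
       ALPHA_6C = c(547, 559))
}

#' Classify a set of peak calls into a heme spectral state
#'
#' Ordered decision rules over the detected peaks:
#' \enumerate{
#'   \item no Soret-class peak: \code{APO_NO_HEME} (apoprotein);
#'   \item a Soret peak near 436 nm: \code{FREE_HEMIN};
#'   \item a Soret peak near 418 nm together with beta (525 nm) and alpha
#'     (553 nm) bands: \code{FERROUS_6C};
#'   \item a Soret peak near 398 nm: \code{FERROUS_5C_NO} (no alpha/beta
#'     requirement);
#'   \item a Soret peak near 408 nm: \code{FERRIC_HIS_LIGATED};
#'   \item otherwise \code{AMBIGUOUS}, with the partially matching
#'     candidate states listed in the rationale.
#' }
#' The 6-coordinate test precedes the 5c-NO and ferric tests so that the
#' alpha/beta requirement disambiguates a 418 nm Soret from 408/398 nm
#' shoulders. The transient 6c NO intermediate (~420 nm) is deliberately
#' not a built-in state; custom \code{windows} can represent it.
#'
#' @param peaks An \code{"hnox_peaks"} data frame from [detect_peaks()].
#' @param windows Classification windows, see [heme_state_windows()].
#' @return An object of class \code{"hnox_state"}: list with \code{state},
#'   \code{supporting_peaks} and \code{rationale}.
#' @export
classify_heme_state <- function(peaks, windows = heme_state_windows()) {
  soret <- peaks[peaks$band_class == "SORET", , drop = FALSE]
  beta <- peaks[peaks$band_class == "BETA", , drop = FALSE]
  alpha <- peaks[peaks$band_class == "ALPHA", , drop = FALSE]
  in_win <- function(p, win) p[p$lambda_max >= win[1L] & p$lambda_max <= win[2L],
                               , drop = FALSE]
  call <- function(state, support, rationale)
    structure(list(state = state, supporting_peaks = support,
                   rationale = rationale), class = "hnox_state")
  if (nrow(soret) == 0L)
    return(call("APO_NO_HEME", peaks[0L, ],
                "no Soret-class peak above the prominence threshold"))
  hem <- in_win(soret, windows$FREE_HEMIN)
  if (nrow(hem))
    return(call("FREE_HEMIN", hem,
                sprintf("Soret at %.1f nm in the free-hemin window", hem$lambda_max[1L])))
  f6 <- in_win(soret, windows$FERROUS_6C)
  b6 <- in_win(beta, windows$BETA_6C)
  a6 <- in_win(alpha, windows$ALPHA_6C)
  if (nrow(f6) && nrow(b6) && nrow(a6))
    return(call("FERROUS_6C", rbind(f6, b6, a6),
                sprintf("Soret at %.1f nm with beta/alpha bands at %.1f/%.1f nm",
                        f6$lambda_max[1L], b6$lambda_max[1L], a6$lambda_max[1L])))
  no5 <- in_win(soret, windows$FERROUS_5C_NO)
  if (nrow(no5))
    return(call("FERROUS_5C_NO", no5,
                sprintf("Soret at %.1f nm in the 5c-nitrosyl window", no5$lambda_max[1L])))
  fe3 <- in_win(soret, windows$FERRIC_HIS_LIGATED)
  if (nrow(fe3))
    return(call("FERRIC_HIS_LIGATED", fe3,
                sprintf("Soret at %.1f nm in the ferric window", fe3$lambda_max[1L])))
  cands <- character()
  if (nrow(f6)) cands <- c(cands, "FERROUS_6C (Soret matches but alpha/beta bands missing)")
  for (st in c("FERRIC_HIS_LIGATED", "FERROUS_5C_NO", "FREE_HEMIN"))
    if (nrow(in_win(soret, windows[[st]]))) cands <- c(cands, st)
  if (length(cands) == 0L)
    cands <- sprintf("no state window contains the Soret peak at %.1f nm",
                     soret$lambda_max[1L])
  call("AMBIGUOUS", soret,
       paste0("conflicting candidates: ", paste(cands, collapse = "; ")))
}

#' @export
print.hnox_state <- function(x, ...) {
  cat("Heme state: ", x$state, "\n  ", x$rationale, "\n", sep = "")
  invisible(x)
}

#' Classify a spectrum into a heme spectral state
#'
#' Convenience wrapper: optional smoothing, peak detection, then
#' [classify_heme_state()].
#'
#' @param x An \code{"hnox_spectrum"}. The grid must cover at least
#'   350-600 nm, the measured window the state assignments were derived
#'   from, and carry at least 20 points.
#' @param min_prominence Minimum peak prominence (AU).
#' @param smooth Logical; apply [smooth_spectrum()] first.
#' @param window,order Smoothing parameters.
#' @param windows State windows, see [heme_state_windows()].
#' @return An \code{"hnox_state"}.
#' @export
classify_spectrum <- function(x, min_prominence = 0.02, smooth = TRUE,
                              window = 11L, order = 2L,
                              windows = heme_state_windows()) {
  stopifnot(inherits(x, "hnox_spectrum"))
  if (length(x$wavelength) < 20L)
    stop("spectrum has fewer than 20 points")
  if (min(x$wavelength) > 350 || max(x$wavelength) < 600)
    stop("classification requires grid coverage of at least 350-600 nm")
  if (smooth) x <- smooth_spectrum(x, window, order)
  classify_heme_state(detect_peaks(x, min_prominence = min_prominence))
}

#' Construct an NO-titration series
#'
#' @param concentrations Non-decreasing NO-donor concentrations (uM DEA
#'   NONOate), one per step.
#' @param spectra List of \code{"hnox_spectrum"} objects, one per step.
#' @return An object of class \code{"hnox_titration"}.
#' @export
titration_series <- function(concentrations, spectra) {
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) != length(spectra))
    stop("one spectrum per concentration step is required")
  if (length(concentrations) < 3L)
    stop("a titration series needs at least 3 steps")
  if (any(diff(concentrations) < 0))
    stop("concentrations must be non-decreasing")
  stopifnot(all(vapply(spectra, inherits, logical(1), "hnox_spectrum")))
  structure(list(concentrations = concentrations, spectra = spectra),
            class = "hnox_titration")
}

#' Detect NO saturation in a titration series
#'
#' Saturation is declared at the smallest step index from which on all
#' consecutive spectral changes (max-norm absorbance difference, after
#' resampling to the first spectrum's grid if needed) stay below
#' \code{tolerance} — mirroring the operational criterion that further NO
#' donor addition causes no further spectral change. Indices are 1-based: a
#' series of identical spectra saturates at index 1.
#'
#' @param series An \code{"hnox_titration"}.
#' @param tolerance Max-norm tolerance in AU.
#' @return An object of class \code{"hnox_saturation"}: list with
#'   \code{saturated}, \code{saturation_index}, \code{saturation_concentration}
#'   (uM), \code{max_residual_change} (AU, largest consecutive change at or
#'   beyond the saturation index) and \code{step_changes} (all consecutive
#'   max-norm differences).
#' @export
analyze_titration <- function(series, tolerance = 0.005) {
  stopifnot(inherits(series, "hnox_titration"))
  grid <- series$spectra[[1L]]$wavelength
  mats <- vapply(series$spectra, function(s) {
    if (length(s$wavelength) == length(grid) &&
        all(abs(s$wavelength - grid) < 1e-9)) s$absorbance
    else stats::approx(s$wavelength, s$absorbance, xout = grid, rule = 2L)$y
  }, numeric(length(grid)))
  n <- ncol(mats)
  d <- vapply(seq_len(n - 1L), function(i)
    max(abs(mats[, i + 1L] - mats[, i])), numeric(1))
  below <- d < tolerance
  # smallest i with all steps from i on below tolerance
  idx <- NA_integer_
  run <- rev(cumprod(rev(below)))
  if (run[1L] == 1) idx <- 1L
  else if (any(run == 1)) idx <- min(which(run == 1)) else idx <- NA_integer_
  saturated <- !is.na(idx)
  structure(list(
    saturated = saturated,
    saturation_index = idx,
    saturation_concentration = if (saturated) series$concentrations[idx]
                               else NA_real_,
    max_residual_change = if (saturated) max(d[idx:length(d)]) else NA_real_,
    step_changes = d), class = "hnox_saturation")
}

#' @export
print.hnox_saturation <- function(x, ...) {
  if (x$saturated)
    cat("NO saturation at step ", x$saturation_index, " (",
        x$saturation_concentration, " uM donor); residual change ",
        signif(x$max_residual_change, 3), " AU\n", sep = "")
  else cat("No saturation detected within the series\n")
  invisible(x)
}

#' Construct a dissociation (post-NO-saturation) time series
#'
#' @param times Strictly increasing time points (hours).
#' @param spectra List of \code{"hnox_spectrum"} objects, one per time.
#' @return An object of class \code{"hnox_timeseries"}.
#' @export
dissociation_series <- function(times, spectra) {
  times <- as.numeric(times)
  if (length(times) != length(spectra))
    stop("one spectrum per time point is required")
  if (length(times) < 3L)
    stop("a dissociation series needs at least 3 time points")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  stopifnot(all(vapply(spectra, inherits, logical(1), "hnox_spectrum")))
  structure(list(times = times, spectra = spectra),
            class = "hnox_timeseries")
}

#' Detect the return of the ferric Soret peak after NO saturation
#'
#' Classifies each spectrum in the series and reports the first time point
#' at which the ferric His-ligated state (Soret back at 408 nm) is called —
#' the spectral signature of slow NO release from the heme.
#'
#' @param series An \code{"hnox_timeseries"}.
#' @param ... Passed to [classify_spectrum()].
#' @return List with \code{recovered} (logical), \code{recovery_time}
#'   (first ferric time point, NA if none) and \code{states} (per-time
#'   state calls).
#' @export
analyze_dissociation <- function(series, ...) {
  stopifnot(inherits(series, "hnox_timeseries"))
  states <- vapply(series$spectra,
                   function(s) classify_spectrum(s, ...)$state, character(1))
  hit <- which(states == "FERRIC_HIS_LIGATED")
  list(recovered = length(hit) > 0L,
       recovery_time = if (length(hit)) series$times[hit[1L]] else NA_real_,
       states = stats::setNames(states, series$times))
}
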