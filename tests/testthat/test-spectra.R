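grid1 <- seq(350, 600, by = 1)

test_that("moving least-squares smoothing reproduces low-order polynomials", {
  flat <- spectrum(grid1, rep(0.2, length(grid1)))
  expect_equal(smooth_spectrum(flat)$absorbance, flat$absorbance)

  quad <- spectrum(grid1, 1e-5 * (grid1 - 450)^2 + 0.1)
  expect_equal(smooth_spectrum(quad, window = 11, order = 2)$absorbance,
               quad$absorbance, tolerance = 1e-9)

  expect_error(smooth_spectrum(flat, window = 10), "odd")
  expect_error(smooth_spectrum(flat, window = 5, order = 5), "smaller")
  expect_error(smooth_spectrum(spectrum(1:21, rep(1, 21)), window = 23),
               "exceeds")
})

test_that("smoothing reduces noise substantially on a synthetic band", {
  set.seed(31)
  clean <- 0.5 * exp(-(grid1 - 420)^2 / (2 * 12^2))
  noisy <- clean + rnorm(length(grid1), sd = 0.005)
  sm <- smooth_spectrum(spectrum(grid1, noisy))$absorbance
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(noisy - clean) / rms(sm - clean), 2)
})

test_that("smoothing matches Savitzky-Golay filtering on interior points", {
  set.seed(32)
  y <- 0.4 * exp(-(grid1 - 410)^2 / 200) + rnorm(length(grid1), sd = 0.01)
  ours <- smooth_spectrum(spectrum(grid1, y), window = 11, order = 2)
  ref <- signal::sgolayfilt(y, p = 2, n = 11)
  interior <- 6:(length(y) - 5)
  expect_equal(ours$absorbance[interior], ref[interior], tolerance = 1e-8)
})

test_that("peak detection recovers synthetic band positions", {
  tpl <- spectrum_template("ferric")
  tpl$bands <- tpl$bands[1L, ]  # isolated 408 nm Soret, sigma 12, 0.5 AU
  p <- detect_peaks(gen_spectrum(tpl))
  expect_equal(nrow(p), 1L)
  expect_equal(p$band_class, "SORET")
  expect_lt(abs(p$lambda_max - 408), 0.5)

  flat <- spectrum(grid1, rep(0.05, length(grid1)))
  expect_equal(nrow(detect_peaks(flat)), 0L)

  ab <- spectrum_template("ferrous")
  ab$bands <- ab$bands[2:3, ]  # beta 525 + alpha 553 only
  p2 <- detect_peaks(gen_spectrum(ab), min_prominence = 0.02)
  expect_setequal(p2$band_class, c("BETA", "ALPHA"))
  expect_lt(abs(p2$lambda_max[p2$band_class == "BETA"] - 525), 1)
  expect_lt(abs(p2$lambda_max[p2$band_class == "ALPHA"] - 553), 1)

  expect_error(detect_peaks(flat, region = c(100, 200)), "within")
})

test_that("peak positions are accurate for isolated noisy bands at SNR 20", {
  errs <- c()
  for (i in 1:120) {
    set.seed(1000 + i)
    ctr <- runif(1, 390, 530)
    sb <- sample(c(6, 10, 14), 1)
    v <- 0.03 + 0.5 * exp(-(grid1 - ctr)^2 / (2 * sb^2)) +
      rnorm(length(grid1), sd = 0.5 / 20)
    p <- detect_peaks(smooth_spectrum(spectrum(grid1, v)),
                      min_prominence = 0.1)
    errs <- c(errs, abs(p$lambda_max[1L] - ctr))
  }
  expect_lt(sqrt(mean(errs^2)), 0.5)
  expect_lt(max(errs), 2)
})

test_that("noise-free state templates classify perfectly", {
  for (s in c("ferric", "ferrous", "no_5c", "hemin", "apo")) {
    cl <- classify_spectrum(gen_spectrum(spectrum_template(s)))
    expect_equal(cl$state, expected_state(s))
  }
  # flat spectrum: apoprotein (no Soret peak at all)
  flat <- spectrum(grid1, rep(0.02, length(grid1)))
  expect_equal(classify_spectrum(flat)$state, "APO_NO_HEME")
})

test_that("a 418 nm Soret without alpha/beta bands is ambiguous", {
  tpl <- spectrum_template("ferrous")
  tpl$bands <- tpl$bands[1L, ]  # Soret only
  cl <- classify_spectrum(gen_spectrum(tpl))
  expect_equal(cl$state, "AMBIGUOUS")
  expect_match(cl$rationale, "FERROUS_6C")
})

test_that("classification stays above 95% accuracy at 0.01 AU noise", {
  states <- c("ferric", "ferrous", "no_5c", "hemin", "apo")
  ok <- 0L
  n <- 0L
  for (i in 1:40) {
    for (s in states) {
      sp <- gen_spectrum(spectrum_template(s, noise_sd = 0.01),
                         seed = i * 10L + match(s, states))
      n <- n + 1L
      ok <- ok + (classify_spectrum(sp)$state == expected_state(s))
    }
  }
  expect_gte(ok / n, 0.95)
})

test_that("titration saturation matches the closed-form isotherm oracle", {
  conc <- seq(0, 1000, by = 25)
  K <- 50
  ser <- gen_titration(K, conc, seed = 1)
  res <- analyze_titration(ser, tolerance = 0.005)

  # independent oracle: bound fraction f = c/(K+c); consecutive spectral
  # change is (f_{i+1}-f_i) * max|no5c - ferrous| with both clean end-state
  # curves written out from the Gaussian band sums directly
  v0 <- 0.03 - 2e-5 * (grid1 - 350) +
    0.55 * exp(-(grid1 - 418)^2 / (2 * 10^2)) +
    0.055 * exp(-(grid1 - 525)^2 / (2 * 7^2)) +
    0.065 * exp(-(grid1 - 553)^2 / (2 * 7^2))
  v1 <- 0.03 - 2e-5 * (grid1 - 350) +
    0.42 * exp(-(grid1 - 398)^2 / (2 * 13^2))
  D <- max(abs(v1 - v0))
  f <- conc / (K + conc)
  d <- diff(f) * D
  ok_from <- rev(cumprod(rev(d < 0.005)))
  oracle_index <- min(which(ok_from == 1))

  expect_true(res$saturated)
  expect_equal(res$saturation_index, oracle_index)
  expect_equal(res$saturation_concentration, conc[oracle_index])
})

test_that("titration handles degenerate series and scaling invariance", {
  sp <- gen_spectrum(spectrum_template("ferrous"))
  same <- titration_series(c(0, 10, 20), list(sp, sp, sp))
  res <- analyze_titration(same)
  expect_true(res$saturated)
  expect_equal(res$saturation_index, 1L)

  # strictly diverging series never saturates
  div <- titration_series(0:3, lapply(0:3, function(k)
    spectrum(grid1, rep(0.1 * (1.5^k), length(grid1)))))
  expect_false(analyze_titration(div, tolerance = 0.01)$saturated)

  # uniform absorbance scaling with equally scaled tolerance is invariant
  ser <- gen_titration(50, seq(0, 800, 40), seed = 5)
  scaled <- ser
  scaled$spectra <- lapply(ser$spectra, function(s)
    spectrum(s$wavelength, s$absorbance * 3, s$label))
  r1 <- analyze_titration(ser, tolerance = 0.005)
  r2 <- analyze_titration(scaled, tolerance = 0.015)
  expect_equal(r2$saturation_index, r1$saturation_index)

  expect_error(titration_series(c(0, 10), list(sp, sp)), "3 steps")
  expect_error(titration_series(c(10, 0, 20), list(sp, sp, sp)),
               "non-decreasing")
})

test_that("reduced NO affinity needs more donor to reach saturation", {
  conc <- seq(0, 2000, by = 50)
  wt <- analyze_titration(gen_titration(50, conc, seed = 7,
                                        noise_sd = 5e-4))
  mut <- analyze_titration(gen_titration(100, conc, seed = 8,
                                         noise_sd = 5e-4))
  expect_true(wt$saturated && mut$saturated)
  expect_gte(mut$saturation_concentration, wt$saturation_concentration)
})

test_that("dissociation recovery is detected at the classifier crossover", {
  k <- log(2) / 2.5
  times <- seq(0, 12, by = 0.5)
  ser <- gen_dissociation(k, times, seed = 2, noise_sd = 0.003)
  res <- analyze_dissociation(ser)
  expect_true(res$recovered)

  # oracle: classify the clean mixtures on the same time grid
  oracle_states <- vapply(seq_along(times), function(i) {
    frac <- 1 - exp(-k * times[i])
    clean <- gen_dissociation(k, c(times[i], times[i] + 1, times[i] + 2),
                              seed = 99)$spectra[[1L]]
    classify_spectrum(clean)$state
  }, character(1))
  oracle_time <- times[min(which(oracle_states == "FERRIC_HIS_LIGATED"))]
  expect_lte(abs(res$recovery_time - oracle_time), 0.5)

  # the 398 nm state precedes recovery
  expect_equal(unname(res$states[1L]), "FERROUS_5C_NO")
})

test_that("dissociation edge cases behave", {
  # never-ferric series
  sp398 <- gen_spectrum(spectrum_template("no_5c"))
  still <- dissociation_series(c(0, 1, 2), list(sp398, sp398, sp398))
  res <- analyze_dissociation(still)
  expect_false(res$recovered)
  expect_true(is.na(res$recovery_time))

  # already ferric at t = 0
  spf <- gen_spectrum(spectrum_template("ferric"))
  done <- dissociation_series(c(0, 1, 2), list(spf, spf, spf))
  expect_equal(analyze_dissociation(done)$recovery_time, 0)

  expect_error(dissociation_series(c(0, 1), list(spf, spf)), "3 time points")
  expect_error(dissociation_series(c(0, 0, 1), list(spf, spf, spf)),
               "strictly increasing")
})

test_that("faster NO release recovers the ferric state sooner", {
  times <- seq(0, 12, by = 0.5)
  fast <- analyze_dissociation(gen_dissociation(log(2) / 2.5, times,
                                                seed = 3, noise_sd = 5e-4))
  slow <- analyze_dissociation(gen_dissociation(log(2) / 6, times,
                                                seed = 4, noise_sd = 5e-4))
  expect_true(fast$recovered)
  expect_true(fast$recovery_time < slow$recovery_time || !slow$recovered)
})

test_that("spectrum files round-trip through CSV", {
  sp <- gen_spectrum(spectrum_template("ferric", noise_sd = 0.005), seed = 9)
  f <- tempfile(fileext = ".csv")
  write_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(back$wavelength, sp$wavelength)
  expect_equal(back$absorbance, sp$absorbance, tolerance = 1e-12)

  # headerless TSV
  f2 <- tempfile(fileext = ".tsv")
  writeLines(paste(sp$wavelength, sp$absorbance, sep = "\t"), f2)
  back2 <- read_spectrum(f2)
  expect_equal(back2$absorbance, sp$absorbance, tolerance = 1e-12)
})
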