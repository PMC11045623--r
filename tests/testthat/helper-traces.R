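# In-memory trace builders shared across the suite. Fixtures are always
# generated in code; mzML files only appear where the reader path itself is
# under test.

eic_from <- function(rt, intensity, ...) {
  atscreen:::new_eic(rt, intensity, ...)
}

# noiseless Gaussian on a flat baseline
gaussian_eic <- function(apex = 5, height = 1000, sigma = 0.05,
                         baseline = 0, spacing = 0.01, rt_range = c(3, 7),
                         noise_sd = 0, seed = NULL) {
  sm <- make_chromatogram(
    tibble::tibble(mz = 100, apex_rt = apex, height = height,
                   sigma = sigma, asymmetry = 0),
    rt_range = rt_range, spacing = spacing, baseline = baseline,
    noise_sd = noise_sd, seed = seed)
  extract_eic(sm, 100, 5, analyte_id = "g")
}

flat_stats <- function(baseline = 0, noise = 0) {
  structure(list(baseline = baseline, noise = noise,
                 quantile_used = 0.25, lod = baseline + 3 * noise,
                 loq = baseline + 10 * noise,
                 triggers = c(zigzag_exceeded = FALSE,
                              rmse_exceeded = FALSE, ratio_too_low = FALSE),
                 degenerate = FALSE),
            class = "ats_baseline")
}

# two-analyte, three-IS-free minimal target set used by pipeline tests
tiny_targets <- function() {
  tibble::tibble(analyte_id = c("A1", "A2"),
                 mz = c(243.1743, 252.0933),
                 expected_rt = c(4.0, 7.0),
                 is_id = "IS1")
}

tiny_is <- function() {
  tibble::tibble(is_id = "IS1", mz = 301.1, expected_rt = 6.0,
                 height = 5e4)
}

# background fixture realising any combination of the three baseline
# triggers (see test-baseline.R for the construction rationale)
make_bg_fixture <- function(zz_fail, rmse_fail, ratio_fail) {
  n <- 120
  y <- rep(100, n)
  if (rmse_fail) y[1:30] <- seq(55, 95, length.out = 30)
  if (!ratio_fail) {
    y[110:114] <- y[110:114] + 2000 * dnorm(seq(-2, 2, 1)) / dnorm(0)
  }
  if (zz_fail) y[40:83] <- rep(c(240, 100), 22)
  eic_from(seq(0, by = 0.01, length.out = n), y, is_background = TRUE)
}
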