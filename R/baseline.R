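# Baseline, noise, and in-sample LOD/LOQ from the background EIC.
#
# The baseline is normally the 25% intensity quantile of the background
# trace. Three triggers guard that choice; if any fails, the trace is
# treated as noisy and the stricter 80% quantile defines an elevated
# baseline instead:
#   A  zigzag fraction of the background below zigzag_trigger_threshold
#   B  relative RMSE of the baseline-defining intensities about the
#      baseline below background_rmse_threshold
#   C  max intensity over the 25% quantile above minimum_background_ratio
# Noise is the standard deviation of the baseline-defining intensities.
# baseline + 3*noise and + 10*noise are intensity thresholds only (peak
# acceptance), not final quantitative limits.

#' Estimate baseline, noise, and in-sample LOD/LOQ
#'
#' @param bg A background (widened-window) `ats_eic` with >= 10 points.
#' @param params [ats_params()].
#' @return A list of class `ats_baseline`: `baseline`, `noise`,
#'   `quantile_used`, `lod`, `loq`, `triggers` (named logical vector of
#'   trigger failures), `degenerate`.
#' @export
estimate_baseline <- function(bg, params = ats_params()) {
  stopifnot(inherits(bg, "ats_eic"))
  if (is_smoothed(bg)) {
    stop("baseline estimation consumes the raw background EIC", call. = FALSE)
  }
  y <- bg$intensity
  if (nrow(bg) < 10) {
    stop("background EIC needs at least 10 points", call. = FALSE)
  }
  if (all(y == 0)) {
    return(structure(list(baseline = 0, noise = 0,
                          quantile_used = params$higher_background_quantile,
                          lod = 0, loq = 0,
                          triggers = c(zigzag_exceeded = FALSE,
                                       rmse_exceeded = FALSE,
                                       ratio_too_low = TRUE),
                          degenerate = TRUE),
                     class = "ats_baseline"))
  }
  q25 <- unname(quantile(y, params$normal_background_quantile, type = 7))
  base_set <- y[y <= q25]
  prov_noise <- if (length(base_set) > 1) sd(base_set) else 0

  # trigger A: zigzag coverage, judged against the provisional baseline
  zz <- zigzag_fraction(bg, q25, prov_noise, params)
  zigzag_exceeded <- zz >= params$zigzag_trigger_threshold
  # trigger B: relative RMSE of baseline-defining intensities about baseline
  rmse_exceeded <- if (q25 > 0) {
    sqrt(mean((base_set - q25)^2)) / q25 >= params$background_rmse_threshold
  } else {
    # a zero baseline with any spread cannot satisfy a relative criterion
    any(base_set != q25)
  }
  # trigger C: dynamic range of the trace over its low quantile
  ratio_too_low <- if (q25 > 0) {
    max(y) / q25 <= params$minimum_background_ratio
  } else TRUE

  triggers <- c(zigzag_exceeded = zigzag_exceeded,
                rmse_exceeded = rmse_exceeded,
                ratio_too_low = ratio_too_low)
  if (any(triggers)) {
    qu <- params$higher_background_quantile
  } else {
    qu <- params$normal_background_quantile
  }
  bval <- unname(quantile(y, qu, type = 7))
  bset <- y[y <= bval]
  noise <- if (length(bset) > 1) sd(bset) else 0
  structure(list(baseline = bval, noise = noise, quantile_used = qu,
                 lod = bval + 3 * noise, loq = bval + 10 * noise,
                 triggers = triggers, degenerate = FALSE),
            class = "ats_baseline")
}

#' @export
print.ats_baseline <- function(x, ...) {
  cat(sprintf(
    "<ats_baseline> baseline %.4g (q%.2g), noise %.4g, LOD %.4g, LOQ %.4g\n",
    x$baseline, x$quantile_used, x$noise, x$lod, x$loq))
  if (any(x$triggers)) {
    cat("  failed triggers:",
        paste(names(x$triggers)[x$triggers], collapse = ", "), "\n")
  }
  invisible(x)
}

#' In-sample detection and quantification thresholds
#'
#' @param stats An `ats_baseline`.
#' @return Named numeric `c(lod, loq)` = baseline + 3 * noise and
#'   baseline + 10 * noise.
#' @export
lod_loq <- function(stats) {
  stopifnot(inherits(stats, "ats_baseline"))
  c(lod = stats$baseline + 3 * stats$noise,
    loq = stats$baseline + 10 * stats$noise)
}
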