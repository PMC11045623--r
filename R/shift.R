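# Retention-time drift correction at three levels:
#   B  batch-global: mean shift of all internal standards over all
#      IS-containing samples; the largest |shift| sets the search
#      half-width (never below the LC/GC floor);
#   C  intensity-dependent: column overload makes high concentrations elute
#      earlier; a validated negative trend of apex vs log10(height) over
#      the calibration levels predicts a per-analyte correction;
#   D  per-sample: the apex displacement of the assigned internal standard
#      in that sample.
# The resolved search window combines these; a valid peak found exactly at
# the uncorrected expected retention time overrides the IS-derived shift.

#' Batch-global retention-time shift from internal standards
#'
#' @param is_shifts Numeric vector of observed IS shifts (apex minus
#'   expected, minutes) across all IS and IS-containing samples.
#' @param mode `"LC"` or `"GC"` (sets the window floor).
#' @param params [ats_params()].
#' @return List with `mean_shift`, `halfwidth` (max absolute shift, never
#'   below the mode floor), and `n`.
#' @export
global_shift <- function(is_shifts, mode = c("LC", "GC"),
                         params = ats_params()) {
  mode <- match.arg(mode)
  floor_hw <- if (mode == "LC") params$rt_window_floor_lc else
    params$rt_window_floor_gc
  is_shifts <- is_shifts[is.finite(is_shifts)]
  if (!length(is_shifts)) {
    warning("no internal standard detected anywhere; ",
            "assuming zero global shift")
    return(list(mean_shift = 0, halfwidth = floor_hw, n = 0L))
  }
  list(mean_shift = mean(is_shifts),
       halfwidth = max(max(abs(is_shifts)), floor_hw),
       n = length(is_shifts))
}

#' Intensity-dependent shift trend from calibration levels
#'
#' Regresses the calibration apex retention times on log10 apex height and
#' accepts the trend only when it points the physically plausible way
#' (negative slope: higher loads elute earlier), is significant, and is not
#' explained by an unspecific interfering peak in the IS-only control.
#' Without a control sample the veto is unavailable and a stricter
#' significance level applies.
#'
#' @param cal_peaks Tibble/data frame with columns `apex_rt` and `height`,
#'   one row per calibration level where the analyte was found (>= 3).
#' @param control_peaks Optional peak tibble from the IS-only control
#'   within the analyte window (peaks above the in-sample LOD veto the
#'   trend). `NULL` means no control sample was measured.
#' @param params [ats_params()].
#' @return List with `slope` (minutes per log10 count), `intercept`, and
#'   `p_value`, or `NULL` when no validated trend exists.
#' @export
intensity_shift <- function(cal_peaks, control_peaks = NULL,
                            params = ats_params()) {
  have_control <- !is.null(control_peaks)
  if (is.null(cal_peaks) || nrow(cal_peaks) < 3) return(NULL)
  if (any(cal_peaks$height <= 0)) return(NULL)
  x <- log10(cal_peaks$height)
  if (length(unique(x)) < 2) return(NULL)
  fit <- lm(cal_peaks$apex_rt ~ x)
  sl <- coef(fit)[[2]]
  p <- tryCatch(suppressWarnings(summary(fit)$coefficients[2, 4]),
                error = function(e) NA_real_)
  alpha <- if (have_control) 0.05 else 0.01
  if (!is.finite(sl) || !is.finite(p) || sl >= 0 || p >= alpha) return(NULL)
  if (have_control && nrow(control_peaks) > 0) return(NULL)  # unspecific veto
  list(slope = sl, intercept = coef(fit)[[1]], p_value = p)
}

#' Per-sample shift from the assigned internal standard
#'
#' @param is_peak One-row peak tibble for the assigned IS in this sample,
#'   or `NULL` when the IS was not found.
#' @param expected_is_rt Expected IS retention time (minutes).
#' @return List with `shift` (minutes; 0 when the IS is missing) and
#'   `fallback` (`TRUE` when the global shift must stand in).
#' @export
sample_is_shift <- function(is_peak, expected_is_rt) {
  if (is.null(is_peak) || !nrow(is_peak)) {
    return(list(shift = 0, fallback = TRUE))
  }
  list(shift = is_peak$apex_rt[1] - expected_is_rt, fallback = FALSE)
}

#' Resolve the analyte search window for one sample
#'
#' Centres the window on the consensus retention time displaced by the
#' per-sample IS shift and, when a validated intensity trend and a measured
#' height are available, the trend's prediction. The window spans the
#' search half-width and is trimmed to the reference-guided retention-time
#' range extended by the same half-width.
#'
#' @param consensus `ats_consensus` for the analyte.
#' @param halfwidth Search half-width from [global_shift()].
#' @param is_shift Per-sample IS shift (minutes), from [sample_is_shift()].
#' @param trend Optional trend from [intensity_shift()].
#' @param measured_height Optional apex height used to evaluate the trend.
#' @return List with `expected_rt` (shift-corrected) and `window`.
#' @export
resolve_window <- function(consensus, halfwidth, is_shift = 0, trend = NULL,
                           measured_height = NULL) {
  stopifnot(inherits(consensus, "ats_consensus"))
  exp_rt <- consensus$expected_rt + is_shift
  if (!is.null(trend) && !is.null(measured_height) &&
      is.finite(measured_height) && measured_height > 0) {
    pred <- trend$intercept + trend$slope * log10(measured_height)
    exp_rt <- exp_rt + (pred - consensus$expected_rt)
  }
  win <- c(exp_rt - halfwidth, exp_rt + halfwidth)
  lim <- c(consensus$rt_range[1] - halfwidth,
           consensus$rt_range[2] + halfwidth)
  win <- c(max(win[1], lim[1]), min(win[2], lim[2]))
  if (win[2] < win[1]) win <- lim
  list(expected_rt = exp_rt, window = win)
}
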