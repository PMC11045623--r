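#' Workflow analysis parameters
#'
#' Builds the full set of user-tunable parameters controlling EIC
#' processing, baseline estimation, peak walking, shift correction,
#' screening gates, and calibration acceptance. Every argument has the
#' workflow's default; pass only what you want to change.
#'
#' @param background_extension_factor Widening factor applied to the analyte
#'   search window to obtain the background EIC window (>= 1).
#' @param zigzag_trigger_threshold Maximum tolerated fraction of the
#'   background EIC flagged as zigzag before the stricter baseline quantile
#'   is used.
#' @param minimum_background_ratio Minimum ratio of maximum intensity to the
#'   25% intensity quantile for the normal baseline quantile to apply.
#' @param normal_background_quantile Baseline quantile for well-behaved
#'   backgrounds (in (0,1)).
#' @param higher_background_quantile Baseline quantile for noisy backgrounds;
#'   must exceed `normal_background_quantile`.
#' @param background_rmse_threshold Maximum relative RMSE of the
#'   baseline-defining intensities about the baseline.
#' @param intensity_factor_decrease Fractional drop relative to the last
#'   peak-assigned intensity that counts as a continued peak descent.
#' @param intensity_factor_increase Fractional rise relative to the last
#'   peak-assigned intensity that starts the new-peak counter.
#' @param density_factor Multiple of the data density tolerated as a
#'   non-decreasing plateau inside one peak flank.
#' @param increase_density_fraction Fraction of the data density a sustained
#'   rise may last before the walk terminates at a new-peak boundary.
#' @param min_peak_points Peaks with this many points or fewer are tagged
#'   CHECK.
#' @param rt_window_floor_lc,rt_window_floor_gc Minimum retention-time
#'   search half-width (minutes) for LC and GC runs.
#' @param confirming_ratio_tolerance Allowed fractional deviation of the
#'   measured confirming/quantifier intensity ratio from its expected value.
#' @param minimum_cutoff_intensity_factor Fraction of the tallest reference
#'   peak height below which fluctuating shapes are fully tolerated and the
#'   peak-splitting step is bypassed.
#' @param use_MINDIST Switch the SAX/MINDIST shape gate on during screening.
#' @param mindist_ceiling Maximum accepted MINDIST between a sample peak's
#'   SAX sequence and the consensus shape when `use_MINDIST` is on.
#' @param min_r2 Minimum coefficient of determination for an accepted
#'   calibration.
#' @param max_error_quant Maximum accepted median quantification error
#'   (fraction, not percent).
#' @param min_cal_points Minimum calibration levels retained after trimming.
#' @param blank_fraction_threshold Fraction of solvent blanks with analyte
#'   response above which blank subtraction is applied.
#' @param blank_multiplier Samples must exceed this multiple of the blank
#'   mean to escape the masked-by-background tag.
#' @param sax_alphabet_size Alphabet size for SAX encoding (2..20).
#' @param ba_limit_multiplier Multiplier on the SD of differences for
#'   Bland-Altman agreement limits.
#' @param mz_tol_default Default m/z extraction tolerance.
#' @param mz_tol_unit `"ppm"` or `"Da"`.
#' @param zigzag_min_run Minimum length of an alternating high/low run
#'   counted as zigzag.
#' @param shift_exact_match_scans Residual (in scan spacings) within which a
#'   peak at the uncorrected expected retention time overrides the
#'   IS-derived shift.
#' @param smoothing Smoothing scheme for shape analysis: `"interp_ma"`
#'   (interpolate to half spacing then 5-point moving average) or `"ma"`
#'   (moving average only).
#' @param response_type Quantify on `"area"` or `"height"`.
#' @param iqr_multiplier Fence multiplier for reference-control IQR
#'   validation.
#'
#' @return A list of class `ats_params`.
#' @export
#' @examples
#' p <- ats_params(zigzag_trigger_threshold = 0.3)
#' p$zigzag_trigger_threshold
ats_params <- function(background_extension_factor = 1.5,
                       zigzag_trigger_threshold = 0.25,
                       minimum_background_ratio = 3,
                       normal_background_quantile = 0.25,
                       higher_background_quantile = 0.80,
                       background_rmse_threshold = 0.10,
                       intensity_factor_decrease = 0.40,
                       intensity_factor_increase = 0.40,
                       density_factor = 5,
                       increase_density_fraction = 0.25,
                       min_peak_points = 7,
                       rt_window_floor_lc = 0.5,
                       rt_window_floor_gc = 0.1,
                       confirming_ratio_tolerance = 0.20,
                       minimum_cutoff_intensity_factor = 0.001,
                       use_MINDIST = FALSE,
                       mindist_ceiling = 2.0,
                       min_r2 = 0.95,
                       max_error_quant = 0.30,
                       min_cal_points = 4,
                       blank_fraction_threshold = 1 / 3,
                       blank_multiplier = 3,
                       sax_alphabet_size = 7,
                       ba_limit_multiplier = 1.96,
                       mz_tol_default = 5,
                       mz_tol_unit = "ppm",
                       zigzag_min_run = 4,
                       shift_exact_match_scans = 1,
                       smoothing = "interp_ma",
                       response_type = "area",
                       iqr_multiplier = 1.5) {
  p <- as.list(environment())
  class(p) <- "ats_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "ats_params"))
  chk <- function(cond, key, msg) {
    if (!cond) stop("parameter `", key, "` ", msg, call. = FALSE)
  }
  qkeys <- c("zigzag_trigger_threshold", "normal_background_quantile",
             "higher_background_quantile", "background_rmse_threshold",
             "increase_density_fraction", "blank_fraction_threshold")
  for (k in qkeys) {
    chk(is.numeric(p[[k]]) && p[[k]] > 0 && p[[k]] < 1, k, "must lie in (0, 1)")
  }
  chk(p$normal_background_quantile < p$higher_background_quantile,
      "normal_background_quantile", "must be below higher_background_quantile")
  chk(p$background_extension_factor >= 1, "background_extension_factor",
      "must be >= 1")
  chk(p$min_cal_points >= 2, "min_cal_points", "must be >= 2")
  chk(p$sax_alphabet_size >= 2 && p$sax_alphabet_size <= 20,
      "sax_alphabet_size", "must lie in [2, 20]")
  chk(p$mz_tol_unit %in% c("ppm", "Da"), "mz_tol_unit",
      "must be \"ppm\" or \"Da\"")
  chk(p$response_type %in% c("area", "height"), "response_type",
      "must be \"area\" or \"height\"")
  chk(p$smoothing %in% c("interp_ma", "ma"), "smoothing",
      "must be \"interp_ma\" or \"ma\"")
  for (k in c("minimum_background_ratio", "intensity_factor_decrease",
              "intensity_factor_increase", "density_factor",
              "min_peak_points", "rt_window_floor_lc", "rt_window_floor_gc",
              "confirming_ratio_tolerance", "minimum_cutoff_intensity_factor",
              "min_r2", "max_error_quant", "blank_multiplier",
              "ba_limit_multiplier", "mz_tol_default", "zigzag_min_run",
              "iqr_multiplier")) {
    chk(is.numeric(p[[k]]) && length(p[[k]]) == 1 && p[[k]] >= 0, k,
        "must be a nonnegative number")
  }
  invisible(p)
}

#' Load workflow parameters from a configuration file
#'
#' Reads a flat key-value configuration (YAML syntax, one `key: value` per
#' line) and overlays it on the [ats_params()] defaults. Unknown keys are an
#' error so typos cannot silently fall back to defaults; out-of-range values
#' fail naming the offending key.
#'
#' @param path Path to the configuration file. An empty or missing-key file
#'   yields all defaults.
#' @return An `ats_params` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(ats_params))
  # the published parameter sheet spells the MINDIST switch with a dot
  if ("use.MINDIST" %in% names(vals)) {
    vals$use_MINDIST <- vals$`use.MINDIST`
    vals$`use.MINDIST` <- NULL
  }
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(ats_params, vals)
}

#' @export
print.ats_params <- function(x, ...) {
  cat("<ats_params> workflow parameters\n")
  nm <- names(x)
  for (k in nm) cat(sprintf("  %-34s %s\n", k, format(x[[k]])))
  invisible(x)
}
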