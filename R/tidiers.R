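#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a calibration fit
#'
#' @param x An `ats_calfit`.
#' @param ... Unused.
#' @return One row per model term with `term` and `estimate`.
#' @export
tidy.ats_calfit <- function(x, ...) {
  tibble(term = c("(Intercept)", "conc"),
         estimate = c(x$intercept, x$slope))[if (x$origin) 2 else 1:2, ]
}

#' One-row summary of a calibration fit
#'
#' @param x An `ats_calfit`.
#' @param ... Unused.
#' @return Tibble with the winning variant, slope, R2, median
#'   quantification error (%), retained/removed level counts, and the
#'   linear-range cutoffs.
#' @export
glance.ats_calfit <- function(x, ...) {
  tibble(variant = x$variant, origin = x$origin, weight = x$weight,
         slope = x$slope, intercept = x$intercept, r.squared = x$r2,
         error_quant = x$error_quant,
         n_levels = nrow(x$included_levels),
         n_removed = nrow(x$removed_levels),
         conc_min = x$y_cutoff, conc_max = x$y_max,
         rr_min = x$x_cutoff, rr_max = x$x_max)
}

#' Tidy a batch result into one row per analyte x sample decision
#'
#' @param x An `ats_result` from [ats_run()].
#' @param ... Unused.
#' @return The screening-hit tibble joined with quantification columns.
#' @export
tidy.ats_result <- function(x, ...) {
  dplyr::left_join(
    x$hits,
    dplyr::select(x$quant, "analyte_id", "sample_id", "concentration",
                  "exclusion", "recovery"),
    by = c("analyte_id", "sample_id"))
}

#' One-row summary of a batch run
#'
#' @param x An `ats_result`.
#' @param ... Unused.
#' @return Counts of decisions, calibrated analytes, and the global shift.
#' @export
glance.ats_result <- function(x, ...) {
  tibble(n_decisions = nrow(x$hits),
         n_detected = sum(x$hits$status == "DETECTED"),
         n_check = sum(x$hits$status == "CHECK"),
         n_calibrated = sum(!vapply(x$calibrations, is.null, logical(1))),
         global_shift = x$shifts$global$mean_shift,
         search_halfwidth = x$shifts$global$halfwidth)
}
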