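#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_hline geom_abline labs scale_fill_manual theme_minimal
#' @importFrom rlang .data
#' @export
ggplot2::autoplot

#' Plot an extracted ion chromatogram
#'
#' @param object An `ats_eic`.
#' @param peaks Optional peak tibble to mark apexes and bounds.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ats_eic <- function(object, peaks = NULL, ...) {
  p <- ggplot(object, aes(.data$rt, .data$intensity)) +
    geom_line(colour = "grey30") +
    labs(x = "retention time [min]", y = "intensity",
         title = sprintf("%s  m/z %.4f", attr(object, "analyte_id"),
                         attr(object, "mz_target"))) +
    theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + geom_point(data = peaks,
                        aes(.data$apex_rt, .data$height),
                        colour = "red", shape = 17, size = 2)
  }
  p
}

#' Plot a calibration fit with its retained and removed levels
#'
#' @param object An `ats_calfit`.
#' @param ... Unused.
#' @return A ggplot of response ratio vs concentration with the fitted
#'   line; removed levels shown hollow.
#' @export
autoplot.ats_calfit <- function(object, ...) {
  inc <- object$included_levels
  rem <- object$removed_levels
  p <- ggplot(inc, aes(.data$conc, .data$rr)) +
    geom_point(size = 2) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "steelblue") +
    labs(x = "concentration [ng/mL]", y = "response ratio",
         title = sprintf("variant %d (R2 %.3f, error %.1f%%)",
                         object$variant, object$r2, object$error_quant)) +
    theme_minimal()
  if (nrow(rem)) {
    p <- p + geom_point(data = rem, shape = 1, size = 2, colour = "red")
  }
  p
}

#' Qualitative screening heatmap
#'
#' The analyte x sample overview: detected / not detected / masked by
#' background (CHECK shown in its own colour).
#'
#' @param result An `ats_result`.
#' @return A ggplot tile map.
#' @export
plot_screening_heatmap <- function(result) {
  stopifnot(inherits(result, "ats_result"))
  d <- dplyr::left_join(result$hits,
                        dplyr::select(result$responses, "analyte_id",
                                      "sample_id", "masked"),
                        by = c("analyte_id", "sample_id"))
  d$call <- ifelse(d$masked, "masked by background",
                   ifelse(d$status == "DETECTED", "TRUE",
                          ifelse(d$status == "CHECK", "CHECK", "FALSE")))
  ggplot(d, aes(.data$sample_id, .data$analyte_id, fill = .data$call)) +
    geom_tile(colour = "white") +
    scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey85",
                                 CHECK = "#fec44f",
                                 `masked by background` = "#de2d26")) +
    labs(x = NULL, y = NULL, fill = NULL) +
    theme_minimal()
}

#' Bland-Altman plot of paired quantifications
#'
#' @param ref,test Paired concentrations.
#' @param params [ats_params()].
#' @return A ggplot with the mean difference and agreement limits.
#' @export
plot_bland_altman <- function(ref, test, params = ats_params()) {
  ba <- bland_altman(ref, test, params)
  ggplot(ba$pairs, aes(.data$mean, .data$diff)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = ba$mean_diff, colour = "steelblue") +
    geom_hline(yintercept = c(ba$lower_limit, ba$upper_limit),
               linetype = "dashed") +
    labs(x = "mean of pair [ng/mL]", y = "difference [ng/mL]") +
    theme_minimal()
}
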