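# Function F: blank masking, matrix correction, reference validation,
# six-variant auto-trimmed linear calibration, concentrations, recoveries.
#
# The calibration is fitted in six variants -- through the origin or free
# intercept, each unweighted, weighted by x, or weighted by 1/x (x = the
# nominal concentration). Per variant the level with the largest Cook's
# distance is dropped iteratively while doing so both lowers the median
# quantification error and raises R2, down to a minimum number of retained
# levels. Variants meeting the R2 and error criteria compete on (1) lowest
# error, (2) widest retained concentration range, (3) highest R2.

#' Mask analyte responses against solvent blanks
#'
#' When the analyte shows a response in more than `blank_fraction_threshold`
#' of all solvent blanks, a system-dependent background is assumed: the
#' blank mean is subtracted from every sample response, and samples whose
#' raw response does not exceed `blank_multiplier` times the blank mean are
#' tagged masked-by-background.
#'
#' @param responses Named or unnamed numeric vector of sample responses.
#' @param blank_responses Numeric vector of responses in the solvent blanks.
#' @param params [ats_params()].
#' @return A tibble with `response` (raw), `adjusted`, and `masked`.
#' @export
blank_mask <- function(responses, blank_responses, params = ats_params()) {
  if (!length(blank_responses)) {
    warning("no solvent blanks in batch; responses passed through unmasked")
    return(tibble(response = responses, adjusted = responses,
                  masked = FALSE))
  }
  detected <- sum(blank_responses > 0, na.rm = TRUE)
  frac <- detected / length(blank_responses)
  if (frac <= params$blank_fraction_threshold) {
    return(tibble(response = responses, adjusted = responses,
                  masked = FALSE))
  }
  bm <- mean(blank_responses, na.rm = TRUE)
  tibble(response = responses,
         adjusted = pmax(responses - bm, 0),
         masked = responses <= params$blank_multiplier * bm)
}

#' Matrix correction factor for one analyte
#'
#' Matrix-matched QC standards are compared to their solvent-based
#' counterparts; the multiplicative factor `median(solvent) /
#' median(matrix)` undoes the average suppression or enhancement when
#' applied to sample response ratios.
#'
#' @param matrix_rr Response ratios of the matrix-matched QC standards.
#' @param solvent_rr Response ratios of the solvent-based references at the
#'   matching concentration.
#' @return The correction factor (1 when either group is absent).
#' @export
matrix_correction <- function(matrix_rr, solvent_rr) {
  if (!length(matrix_rr) || !length(solvent_rr)) {
    message("matrix or solvent reference group absent; factor 1 applied")
    return(1)
  }
  m <- median(matrix_rr, na.rm = TRUE)
  if (!is.finite(m) || m == 0) return(1)
  median(solvent_rr, na.rm = TRUE) / m
}

#' Validate constant-concentration reference controls by IQR fences
#'
#' @param ref_rr Response ratios of the reference controls.
#' @param params [ats_params()] (`iqr_multiplier` sets the fence).
#' @return Logical vector: `TRUE` where the reference is inside
#'   `[Q1 - k*IQR, Q3 + k*IQR]`.
#' @export
validate_references <- function(ref_rr, params = ats_params()) {
  if (length(ref_rr) < 3) {
    warning("fewer than 3 reference controls; all kept")
    return(rep(TRUE, length(ref_rr)))
  }
  q <- quantile(ref_rr, c(0.25, 0.75), type = 7, na.rm = TRUE)
  iqr <- q[2] - q[1]
  ref_rr >= q[1] - params$iqr_multiplier * iqr &
    ref_rr <= q[2] + params$iqr_multiplier * iqr
}

# ---- calibration -----------------------------------------------------------

cal_variants <- tibble(
  variant = 1:6,
  origin = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
  weight = rep(c("none", "x", "1/x"), 2)
)

fit_one_variant <- function(conc, rr, origin, weight) {
  w <- switch(weight, none = rep(1, length(conc)), x = conc, `1/x` = 1 / conc)
  if (any(!is.finite(w) | w <= 0)) return(NULL)
  df <- data.frame(x = conc, y = rr)
  fit <- if (origin) lm(y ~ x + 0, data = df, weights = w) else
    lm(y ~ x, data = df, weights = w)
  slope <- if (origin) coef(fit)[["x"]] else coef(fit)[["x"]]
  intercept <- if (origin) 0 else coef(fit)[["(Intercept)"]]
  if (!is.finite(slope) || slope == 0) return(NULL)
  yhat <- intercept + slope * conc
  sst <- sum((rr - mean(rr))^2)
  r2 <- if (sst > 0) 1 - sum((rr - yhat)^2) / sst else 1
  cpred <- (rr - intercept) / slope
  err <- median(abs((conc - cpred) / conc) * 100)
  list(lm = fit, slope = slope, intercept = intercept, r2 = r2, error = err)
}

#' Median quantification error of a calibration
#'
#' Each retained level's concentration is back-predicted by inverting the
#' fitted line at its response ratio; the error is the median absolute
#' percent deviation `median(|(C_actual - C_predicted) / C_actual| * 100)`.
#'
#' @param fit An `ats_calfit` (or list with `slope`/`intercept`).
#' @param conc,rr Nominal concentrations and response ratios of the levels.
#' @return Error in percent.
#' @export
error_quantification <- function(fit, conc, rr) {
  if (!is.finite(fit$slope) || fit$slope == 0) {
    stop("calibration slope is zero; fit rejected", call. = FALSE)
  }
  cpred <- (rr - fit$intercept) / fit$slope
  median(abs((conc - cpred) / conc) * 100)
}

#' Fit the auto-trimmed calibration for one analyte
#'
#' @param levels Data frame with columns `conc` (nominal concentration) and
#'   `rr` (response ratio), one row per calibration level.
#' @param params [ats_params()].
#' @return An `ats_calfit` (winning variant with trimming history and
#'   linear-range cutoffs), or `NULL` when no variant meets the acceptance
#'   criteria or too few levels exist.
#' @export
fit_calibration <- function(levels, params = ats_params()) {
  levels <- levels[is.finite(levels$conc) & is.finite(levels$rr) &
                     levels$conc > 0, , drop = FALSE]
  if (nrow(levels) < params$min_cal_points) return(NULL)
  results <- list()
  for (v in seq_len(nrow(cal_variants))) {
    origin <- cal_variants$origin[v]
    weight <- cal_variants$weight[v]
    kept <- seq_len(nrow(levels))
    removed <- integer(0)
    fit <- fit_one_variant(levels$conc[kept], levels$rr[kept], origin, weight)
    if (is.null(fit)) next
    while (length(kept) > params$min_cal_points) {
      cd <- cooks.distance(fit$lm)
      cand <- which.max(cd)
      kept2 <- kept[-cand]
      fit2 <- fit_one_variant(levels$conc[kept2], levels$rr[kept2],
                              origin, weight)
      if (is.null(fit2)) break
      if (fit2$error < fit$error && fit2$r2 > fit$r2) {
        removed <- c(removed, kept[cand])
        kept <- kept2
        fit <- fit2
      } else break
    }
    accepted <- fit$r2 >= params$min_r2 &&
      fit$error < params$max_error_quant * 100
    results[[length(results) + 1]] <- list(
      variant = cal_variants$variant[v], origin = origin, weight = weight,
      fit = fit, kept = kept, removed = removed, accepted = accepted)
  }
  results <- Filter(function(r) r$accepted, results)
  if (!length(results)) return(NULL)
  score <- vapply(results, function(r) {
    rng <- diff(range(levels$conc[r$kept]))
    c(r$fit$error, -rng, -r$fit$r2)
  }, numeric(3))
  best <- results[[order(score[1, ], score[2, ], score[3, ])[1]]]
  kept <- best$kept
  structure(list(
    variant = best$variant, origin = best$origin, weight = best$weight,
    slope = best$fit$slope, intercept = best$fit$intercept,
    r2 = best$fit$r2, error_quant = best$fit$error,
    included_levels = levels[kept, , drop = FALSE],
    removed_levels = if (length(best$removed)) {
      cbind(levels[best$removed, , drop = FALSE],
            reason = "cooks_distance_trim")
    } else levels[0, , drop = FALSE],
    x_cutoff = min(levels$rr[kept]), x_max = max(levels$rr[kept]),
    y_cutoff = min(levels$conc[kept]), y_max = max(levels$conc[kept])
  ), class = "ats_calfit")
}

#' @export
print.ats_calfit <- function(x, ...) {
  cat(sprintf(
    "<ats_calfit> variant %d (%s, w=%s): rr = %.4g%s * conc, R2 %.4f, error %.2f%%\n",
    x$variant, if (x$origin) "origin" else "free intercept", x$weight,
    x$slope, if (x$origin) "" else sprintf(" %+.4g", x$intercept), x$r2,
    x$error_quant))
  cat(sprintf("  %d levels retained (%.3g-%.3g ng/mL), %d removed\n",
              nrow(x$included_levels), x$y_cutoff, x$y_max,
              nrow(x$removed_levels)))
  invisible(x)
}

invert_calibration <- function(fit, rr) (rr - fit$intercept) / fit$slope

#' Quantify one screened analyte in one sample
#'
#' @param status Screening status (`DETECTED`, `CHECK`, `NOT_DETECTED`).
#' @param rr Blank-adjusted, matrix-corrected response ratio.
#' @param fit `ats_calfit` for the analyte, or `NULL`.
#' @param masked Was the sample masked by background?
#' @param allow_check Treat CHECK hits as quantifiable (supervised
#'   re-evaluation).
#' @return One-row tibble: `concentration` (ng/mL or `NA`) and `exclusion`
#'   (`none`, `masked_by_background`, `below_calibration`,
#'   `above_calibration`, `check_status`, `not_detected`, `no_calibration`).
#' @export
quantify_sample <- function(status, rr, fit, masked = FALSE,
                            allow_check = FALSE) {
  excl <- "none"
  conc <- NA_real_
  if (masked) {
    excl <- "masked_by_background"
  } else if (identical(status, "NOT_DETECTED")) {
    excl <- "not_detected"
  } else if (identical(status, "CHECK") && !allow_check) {
    excl <- "check_status"
  } else if (is.null(fit)) {
    excl <- "no_calibration"
  } else if (!is.finite(rr)) {
    excl <- "not_detected"
  } else if (rr < fit$x_cutoff) {
    excl <- "below_calibration"
  } else if (rr > fit$x_max) {
    excl <- "above_calibration"
  } else {
    conc <- invert_calibration(fit, rr)
  }
  tibble(concentration = conc, exclusion = excl)
}

#' Recovery relative to valid reference controls
#'
#' @param rr Sample response ratio(s).
#' @param valid_ref_rr Response ratios of the IQR-validated references (the
#'   100% equivalent).
#' @return Recovery in percent (`NA` with a warning when the reference
#'   median is zero).
#' @export
recovery <- function(rr, valid_ref_rr) {
  if (!length(valid_ref_rr)) {
    warning("no valid reference controls; recovery undefined")
    return(rep(NA_real_, length(rr)))
  }
  m <- median(valid_ref_rr, na.rm = TRUE)
  if (!is.finite(m) || m == 0) {
    warning("reference median is zero; recovery undefined")
    return(rep(NA_real_, length(rr)))
  }
  100 * rr / m
}
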