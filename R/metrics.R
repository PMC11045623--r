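# Workflow-comparison metrics: confusion-matrix summaries of annotation
# agreement against a reference workflow, MAPE of paired concentrations,
# and Bland-Altman agreement limits.

#' Sensitivity, specificity, and accuracy from confusion counts
#'
#' @param tp,tn,fp,fn Nonnegative integer counts.
#' @param digits Decimals for the reporting layer (`NULL` for unrounded).
#' @return Tibble with `sensitivity` = TP/(TP+FN), `specificity` =
#'   TN/(TN+FP), `accuracy` = (TP+TN)/n; a zero denominator yields `NA` for
#'   that metric.
#' @export
classification_metrics <- function(tp, tn, fp, fn, digits = 2) {
  stopifnot(all(c(tp, tn, fp, fn) >= 0), tp + tn + fp + fn > 0)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  out <- tibble(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn)
  )
  if (!is.null(digits)) out <- dplyr::mutate(out,
    dplyr::across(dplyr::everything(), ~ round(.x, digits)))
  out
}

#' Build confusion counts from screening hits and ground truth
#'
#' CHECK (and comparable "estimated") statuses count as negative in the
#' fully unsupervised reading; set `check_positive = TRUE` for the
#' supervised re-evaluation scenario.
#'
#' @param hits Tibble with `analyte_id`, `sample_id`, `status`.
#' @param truth Tibble with `analyte_id`, `sample_id`, `present` (logical).
#' @param check_positive Count CHECK as positive.
#' @return Tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(hits, truth, check_positive = FALSE) {
  pos_status <- if (check_positive) c("DETECTED", "CHECK") else "DETECTED"
  m <- dplyr::inner_join(hits, truth, by = c("analyte_id", "sample_id"))
  pos <- m$status %in% pos_status
  tibble(tp = sum(pos & m$present), tn = sum(!pos & !m$present),
         fp = sum(pos & !m$present), fn = sum(!pos & m$present))
}

#' Mean absolute percentage error between paired quantifications
#'
#' @param ref Reference concentrations (> 0).
#' @param test Test concentrations, same length.
#' @return MAPE in percent: `mean(|ref - test| / ref) * 100`.
#' @export
mape <- function(ref, test) {
  stopifnot(length(ref) == length(test), length(ref) > 0)
  if (any(ref <= 0)) stop("reference concentrations must be positive",
                          call. = FALSE)
  mean(abs(ref - test) / ref) * 100
}

#' Bland-Altman agreement limits for paired quantifications
#'
#' @param ref,test Paired concentrations (>= 2 pairs).
#' @param params [ats_params()] (`ba_limit_multiplier`, default 1.96).
#' @return List with `mean_diff`, `lower_limit`, `upper_limit`, `sd_diff`,
#'   and a tibble `pairs` of per-pair `(mean, diff)` for plotting.
#' @export
bland_altman <- function(ref, test, params = ats_params()) {
  stopifnot(length(ref) == length(test), length(ref) >= 2)
  d <- test - ref
  m <- (test + ref) / 2
  md <- mean(d)
  sdd <- sd(d)
  k <- params$ba_limit_multiplier
  list(mean_diff = md, sd_diff = sdd,
       lower_limit = md - k * sdd, upper_limit = md + k * sdd,
       pairs = tibble(mean = m, diff = d))
}
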