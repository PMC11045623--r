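# Function E: the per analyte x sample decision. A candidate peak is
# selected inside the shift-resolved window; gates then decide DETECTED vs
# CHECK (area still integrated, but counted negative in fully unsupervised
# mode): residual shift out of range, strong shape mismatch (MINDIST,
# optional), too few data points, or a missing expected confirming ion.

#' Check confirming ions against a quantifier peak
#'
#' Each confirming ion is screened for presence and for whether a detection
#' can be expected at all: the expected confirmer intensity is the
#' quantifier height times the expected ratio; if that falls below the
#' confirmer's own in-sample LOD the ion cannot be demanded
#' (`not_expected`, no penalty). Otherwise a confirmer peak must co-elute
#' (apex inside the quantifier peak bounds) with a measured
#' confirming/quantifier ratio within the allowed deviation.
#'
#' @param quant_peak One-row peak tibble for the quantifier.
#' @param conf_eics List of raw `ats_eic`s, one per confirming ion.
#' @param expected_ratios Numeric vector of expected confirming/quantifier
#'   intensity ratios.
#' @param conf_stats List of `ats_baseline` per confirming ion.
#' @param params [ats_params()].
#' @return `"confirmed"`, `"not_expected"` (no confirmer demandable), or
#'   `"missing"`.
#' @export
confirmers_check <- function(quant_peak, conf_eics, expected_ratios,
                             conf_stats, params = ats_params()) {
  if (!length(expected_ratios)) return("confirmed")
  stopifnot(length(conf_eics) == length(expected_ratios),
            length(conf_stats) == length(expected_ratios))
  tol <- params$confirming_ratio_tolerance
  outcomes <- character(length(expected_ratios))
  for (i in seq_along(expected_ratios)) {
    expected <- quant_peak$height[1] * expected_ratios[i]
    if (expected < conf_stats[[i]]$lod) {
      outcomes[i] <- "not_expected"
      next
    }
    pks <- find_peaks(conf_eics[[i]], conf_stats[[i]], params)
    hit <- NULL
    if (nrow(pks)) {
      inb <- pks$apex_rt >= quant_peak$start_rt[1] &
        pks$apex_rt <= quant_peak$end_rt[1] &
        pks$height >= conf_stats[[i]]$lod
      if (any(inb)) {
        cand <- pks[inb, , drop = FALSE]
        hit <- cand[which.max(cand$height), , drop = FALSE]
      }
    }
    if (is.null(hit)) {
      outcomes[i] <- "missing"
      next
    }
    ratio <- hit$height[1] / quant_peak$height[1]
    ok <- abs(ratio - expected_ratios[i]) <= tol * expected_ratios[i]
    outcomes[i] <- if (ok) "confirmed" else "missing"
  }
  if (any(outcomes == "missing")) return("missing")
  if (all(outcomes == "not_expected")) return("not_expected")
  "confirmed"
}

screening_hit <- function(analyte_id, sample_id, status, peak = NULL,
                          applied_shift = 0, check_reasons = character(0)) {
  tibble(
    analyte_id = analyte_id, sample_id = sample_id, status = status,
    apex_rt = if (!is.null(peak)) peak$apex_rt[1] else NA_real_,
    height = if (!is.null(peak)) peak$height[1] else NA_real_,
    area = if (!is.null(peak)) peak$area[1] else NA_real_,
    n_points = if (!is.null(peak)) peak$n_points[1] else NA_integer_,
    applied_shift = applied_shift,
    check_reasons = paste(check_reasons, collapse = ";")
  )
}

#' Screen one analyte in one sample
#'
#' Detects peaks on the raw EIC, selects the candidate inside the
#' shift-resolved window, and applies the CHECK gates. A valid peak sitting
#' exactly at the uncorrected expected retention time overrides the
#' IS-derived shift. Intensities at or above the in-sample LOD close to the
#' expected retention time admit zigzag or otherwise non-Gaussian shapes
#' without a shape penalty.
#'
#' @param eic Raw analyte `ats_eic` for this sample.
#' @param stats `ats_baseline` from the matching background EIC.
#' @param consensus `ats_consensus` for the analyte.
#' @param halfwidth Search half-width (minutes) from [global_shift()].
#' @param floor_hw Mode retention-time floor (minutes).
#' @param is_shift Per-sample IS shift (minutes).
#' @param trend Optional intensity trend from [intensity_shift()].
#' @param conf List describing confirming ions:
#'   `list(eics = , ratios = , stats = )`, or `NULL` when none are defined.
#' @param params [ats_params()].
#' @param analyte_id,sample_id Identifiers stamped on the result.
#' @return One-row tibble (`ats_hit` semantics): status `DETECTED`,
#'   `CHECK`, or `NOT_DETECTED`, with area/height/apex and CHECK reasons.
#' @export
screen_sample <- function(eic, stats, consensus, halfwidth,
                          floor_hw = 0.1, is_shift = 0, trend = NULL,
                          conf = NULL, params = ats_params(),
                          analyte_id = NULL, sample_id = NULL) {
  stopifnot(inherits(consensus, "ats_consensus"))
  if (is.null(analyte_id)) analyte_id <- consensus$analyte_id
  if (is.null(sample_id)) sample_id <- attr(eic, "sample_id")
  cutoff <- params$minimum_cutoff_intensity_factor * consensus$max_ref_height
  spacing <- if (nrow(eic) > 1) median(diff(eic$rt)) else 0

  peaks <- find_peaks(eic, stats, params)
  peaks <- split_merged(peaks, eic, cutoff_height = cutoff)

  applied_shift <- is_shift
  res <- resolve_window(consensus, halfwidth, is_shift, trend,
                        measured_height = NULL)
  if (is_shift != 0) {
    # unshifted-exact-match override
    res0 <- resolve_window(consensus, halfwidth, 0)
    pk0 <- select_peak(peaks, consensus$expected_rt, res0$window, cutoff,
                       stats$lod)
    if (!is.null(pk0) &&
        abs(pk0$apex_rt[1] - consensus$expected_rt) <=
          params$shift_exact_match_scans * spacing) {
      res <- res0
      applied_shift <- 0
    }
  }
  pk <- select_peak(peaks, res$expected_rt, res$window, cutoff, stats$lod)
  if (is.null(pk)) {
    return(screening_hit(analyte_id, sample_id, "NOT_DETECTED",
                         applied_shift = applied_shift))
  }
  # refine expected rt with the trend now that a height is measured
  if (!is.null(trend)) {
    res <- resolve_window(consensus, halfwidth, applied_shift, trend,
                          measured_height = pk$height[1])
    pk2 <- select_peak(peaks, res$expected_rt, res$window, cutoff, stats$lod)
    if (!is.null(pk2)) pk <- pk2
  }

  reasons <- character(0)
  width <- consensus$left_width + consensus$right_width
  if (abs(pk$apex_rt[1] - res$expected_rt) > max(width, floor_hw)) {
    reasons <- c(reasons, "shift_out_of_range")
  }
  if (isTRUE(params$use_MINDIST) && !is.null(consensus$shape) &&
      pk$n_points[1] >= 2) {
    near <- abs(eic$rt - res$expected_rt) <= width
    tolerated <- any(eic$intensity[near] >= stats$lod)
    if (!tolerated) {
      shape <- encode_sax(eic$intensity[pk$start_idx[1]:pk$end_idx[1]],
                          params$sax_alphabet_size)
      if (mindist(shape, consensus$shape) > params$mindist_ceiling) {
        reasons <- c(reasons, "shape_mismatch")
      }
    }
  }
  if (pk$n_points[1] <= params$min_peak_points) {
    reasons <- c(reasons, "too_few_points")
  }
  if (!is.null(conf) && length(conf$ratios)) {
    out <- confirmers_check(pk, conf$eics, conf$ratios, conf$stats, params)
    if (out == "missing") reasons <- c(reasons, "confirming_missing")
  }
  status <- if (length(reasons)) "CHECK" else "DETECTED"
  screening_hit(analyte_id, sample_id, status, pk, applied_shift, reasons)
}
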