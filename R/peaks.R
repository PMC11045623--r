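# Local-maxima peak walker. Each peak is seeded at the highest unassigned
# intensity in the search window and grown outward on both flanks:
#   * strictly decreasing values are assigned directly;
#   * a non-decreasing stretch is tolerated for up to
#     density_factor * data_density points ("plateau budget"); the stretch
#     is absorbed into the peak as soon as a value drops more than
#     intensity_factor_decrease below the last assigned intensity;
#   * if the budget runs out first, the flank ends at the plateau start;
#   * a rise of more than intensity_factor_increase above the last assigned
#     intensity starts a second counter; if the rise outlives
#     increase_density_fraction * data_density points the flank ends there
#     (the rise belongs to another peak).
# This admits shoulder bumps and non-Gaussian deformities inside one peak
# while refusing to climb into a neighbour.

peak_row <- function(eic, start_idx, apex_idx, end_idx,
                     plateau_truncated = FALSE) {
  tibble(
    start_idx = start_idx, apex_idx = apex_idx, end_idx = end_idx,
    start_rt = eic$rt[start_idx], apex_rt = eic$rt[apex_idx],
    end_rt = eic$rt[end_idx],
    height = eic$intensity[apex_idx],
    area = if (end_idx > start_idx) integrate_area(eic, start_idx, end_idx)
           else 0,
    n_points = end_idx - start_idx + 1L,
    plateau_truncated = plateau_truncated,
    split_enforced = FALSE
  )
}

walk_flank <- function(y, seed, dir, assigned, plateau_tol, increase_tol,
                       f_dec, f_inc, floor_int = 0) {
  n <- length(y)
  bound <- seed
  last <- y[seed]
  pending <- 0L
  rise <- FALSE
  rise_count <- 0L
  plateau_truncated <- FALSE
  j <- seed
  repeat {
    j <- j + dir
    if (j < 1L || j > n || assigned[j]) break
    v <- y[j]
    if (v <= floor_int) {
      # the flank has reached the baseline band: the peak ends here
      if (v < last) bound <- j
      break
    }
    if (pending == 0L && v < last) {
      bound <- j
      last <- v
    } else if (v <= (1 - f_dec) * last) {
      # decrease deep enough to confirm the peak continues through the bump
      bound <- j
      last <- v
      pending <- 0L
      rise <- FALSE
      rise_count <- 0L
    } else {
      pending <- pending + 1L
      if (v > (1 + f_inc) * last) rise <- TRUE
      if (rise) {
        rise_count <- rise_count + 1L
        if (rise_count > increase_tol) break   # start of another peak
      }
      if (pending > plateau_tol) {             # steady plateau
        plateau_truncated <- TRUE
        break
      }
    }
  }
  list(bound = bound, plateau_truncated = plateau_truncated)
}

#' Detect peaks in an EIC window
#'
#' Runs the plateau/bump-tolerant local-maxima walker over all local maxima
#' inside `window`, in descending seed height, masking points already
#' assigned to a peak. Seeds at or below the baseline stop the enumeration.
#'
#' @param eic A raw `ats_eic`.
#' @param stats `ats_baseline` from the matching background EIC.
#' @param params [ats_params()].
#' @param window Retention-time window `c(lo, hi)`; defaults to the full
#'   trace.
#' @return A tibble of peaks (one row each: indices, retention times,
#'   height, area, point count, flags), sorted by apex retention time.
#' @export
find_peaks <- function(eic, stats, params = ats_params(), window = NULL) {
  stopifnot(inherits(eic, "ats_eic"))
  if (is_smoothed(eic)) {
    stop("peak detection walks the raw EIC", call. = FALSE)
  }
  empty <- peak_row(new_eic(0, 0), 1L, 1L, 1L)[0, ]
  if (nrow(eic) < 3) return(empty)
  if (is.null(window)) window <- range(eic$rt)
  in_win <- eic$rt >= window[1] & eic$rt <= window[2]
  if (!any(in_win)) return(empty)

  y <- eic$intensity
  n <- length(y)
  dens <- max(1, data_density(eic))
  plateau_tol <- params$density_factor * dens
  increase_tol <- params$increase_density_fraction * dens
  assigned <- !in_win   # points outside the window are never claimed
  floor_int <- stats$baseline

  rows <- list()
  repeat {
    cand <- which(!assigned)
    if (!length(cand)) break
    seed <- cand[which.max(y[cand])]
    if (y[seed] <= floor_int || y[seed] <= 0) break
    # the walk need not descend below the baseline band; for tall peaks the
    # band is widened to 0.1% of the seed height above baseline so that
    # noiseless exponential tails terminate
    walk_floor <- stats$baseline +
      max(stats$noise, 1e-3 * (y[seed] - stats$baseline))
    left <- walk_flank(y, seed, -1L, assigned, plateau_tol, increase_tol,
                       params$intensity_factor_decrease,
                       params$intensity_factor_increase, walk_floor)
    right <- walk_flank(y, seed, 1L, assigned, plateau_tol, increase_tol,
                        params$intensity_factor_decrease,
                        params$intensity_factor_increase, walk_floor)
    assigned[left$bound:right$bound] <- TRUE
    if (right$bound - left$bound + 1L >= 3L) {
      rows[[length(rows) + 1L]] <-
        peak_row(eic, left$bound, seed, right$bound,
                 left$plateau_truncated || right$plateau_truncated)
    }
  }
  if (!length(rows)) return(empty)
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$apex_rt)
  out
}

#' Split merged peaks at contact points
#'
#' Where the flanks of two detected peaks meet or overlap, the point of
#' contact is replaced by an enforced split at the intensity minimum (the
#' valley) between the two apexes; both peaks are re-bounded there,
#' flagged, and their areas re-integrated. Peaks below `cutoff_height`
#' bypass splitting: below that intensity, fluctuating patterns are fully
#' tolerated.
#'
#' @param peaks Tibble from [find_peaks()] on `eic`.
#' @param eic The same raw `ats_eic`.
#' @param cutoff_height Peaks shorter than this skip the splitter.
#' @return The peak tibble with enforced splits applied.
#' @export
split_merged <- function(peaks, eic, cutoff_height = 0) {
  stopifnot(inherits(eic, "ats_eic"))
  if (nrow(peaks) < 2) return(peaks)
  peaks <- dplyr::arrange(peaks, .data$apex_rt)
  y <- eic$intensity
  for (i in seq_len(nrow(peaks) - 1)) {
    a <- i
    b <- i + 1
    if (peaks$height[a] < cutoff_height || peaks$height[b] < cutoff_height) {
      next
    }
    # contact: flanks touch (adjacent indices) or overlap
    if (peaks$start_idx[b] - peaks$end_idx[a] > 1L) next
    lo <- peaks$apex_idx[a]
    hi <- peaks$apex_idx[b]
    if (hi - lo < 2L) next
    inner <- (lo + 1L):(hi - 1L)
    valley <- inner[which.min(y[inner])]
    peaks$end_idx[a] <- valley
    peaks$start_idx[b] <- valley
    peaks$split_enforced[c(a, b)] <- TRUE
  }
  changed <- peaks$split_enforced
  if (any(changed)) {
    for (i in which(changed)) {
      peaks$start_rt[i] <- eic$rt[peaks$start_idx[i]]
      peaks$end_rt[i] <- eic$rt[peaks$end_idx[i]]
      peaks$n_points[i] <- peaks$end_idx[i] - peaks$start_idx[i] + 1L
      peaks$area[i] <- if (peaks$end_idx[i] > peaks$start_idx[i]) {
        integrate_area(eic, peaks$start_idx[i], peaks$end_idx[i])
      } else 0
    }
  }
  peaks
}

#' Build a consensus peak from reference-standard detections
#'
#' Unifies the peak characteristics observed for one analyte across the
#' reference (or calibration) samples: the expected retention time is the
#' median apex, the flank widths are median offsets, the retention-time
#' range spans all reference bounds, and the SAX shape is taken from the
#' highest-intensity reference.
#'
#' @param ref_peaks Named list (reference sample id -> one-row peak tibble).
#' @param ref_eics Named list of the matching raw `ats_eic`s.
#' @param analyte_id Analyte identifier.
#' @param heights_by_level Optional named numeric (level concentration ->
#'   apex height) kept for intensity-dependent shift analysis.
#' @param params [ats_params()].
#' @return A list of class `ats_consensus`, or `NULL` when no reference
#'   peak exists (the analyte is unscreenable).
#' @export
build_consensus <- function(ref_peaks, ref_eics, analyte_id = NA_character_,
                            heights_by_level = NULL, params = ats_params()) {
  ref_peaks <- ref_peaks[!vapply(ref_peaks, is.null, logical(1))]
  ref_peaks <- ref_peaks[vapply(ref_peaks, nrow, integer(1)) > 0]
  if (!length(ref_peaks)) return(NULL)
  pk <- dplyr::bind_rows(ref_peaks)
  expected_rt <- median(pk$apex_rt)
  left_width <- median(pk$apex_rt - pk$start_rt)
  right_width <- median(pk$end_rt - pk$apex_rt)
  rt_range <- c(min(pk$start_rt), max(pk$end_rt))
  top <- which.max(pk$height)
  shape <- NULL
  top_id <- names(ref_peaks)[top]
  if (!is.null(ref_eics) && !is.null(top_id) && top_id %in% names(ref_eics)) {
    e <- ref_eics[[top_id]]
    i <- pk$start_idx[top]:pk$end_idx[top]
    if (length(i) >= 2) {
      shape <- encode_sax(e$intensity[i], params$sax_alphabet_size)
    }
  }
  structure(list(analyte_id = analyte_id, expected_rt = expected_rt,
                 left_width = left_width, right_width = right_width,
                 rt_range = rt_range, shape = shape,
                 max_ref_height = max(pk$height),
                 height_by_level = heights_by_level,
                 n_references = nrow(pk)),
            class = "ats_consensus")
}

#' @export
print.ats_consensus <- function(x, ...) {
  cat(sprintf(
    "<ats_consensus> %s: rt %.3f min (-%.3f/+%.3f), range [%.3f, %.3f], %d refs\n",
    x$analyte_id, x$expected_rt, x$left_width, x$right_width,
    x$rt_range[1], x$rt_range[2], x$n_references))
  invisible(x)
}

#' Select the screening candidate among detected peaks
#'
#' Among peaks whose apex lies in `window` and whose height reaches both
#' `cutoff_height` and the in-sample LOD, returns the one with apex nearest
#' `expected_rt`; ties go to the taller peak.
#'
#' @param peaks Tibble from [find_peaks()]/[split_merged()].
#' @param expected_rt Shift-resolved expected retention time (minutes).
#' @param window Search window `c(lo, hi)`.
#' @param cutoff_height Minimum height (use
#'   `minimum_cutoff_intensity_factor * max reference height`).
#' @param lod In-sample limit of detection (counts).
#' @return A one-row peak tibble, or `NULL` when nothing qualifies.
#' @export
select_peak <- function(peaks, expected_rt, window, cutoff_height = 0,
                        lod = 0) {
  if (is.null(peaks) || !nrow(peaks)) return(NULL)
  ok <- peaks$apex_rt >= window[1] & peaks$apex_rt <= window[2] &
    peaks$height >= max(cutoff_height, lod)
  if (!any(ok)) return(NULL)
  cand <- peaks[ok, , drop = FALSE]
  d <- abs(cand$apex_rt - expected_rt)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.max(cand$height[best])]
  cand[best, , drop = FALSE]
}
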