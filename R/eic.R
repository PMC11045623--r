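#' @importFrom tibble tibble as_tibble
#' @importFrom stats approx median quantile sd coef lm qnorm rnorm runif
#'   setNames cooks.distance pnorm na.omit
#' @importFrom utils head tail
NULL

# ---- ScanMap ---------------------------------------------------------------

new_scan_map <- function(sample_id, scan_times, centroids, ms_level = 1L) {
  stopifnot(length(scan_times) == length(centroids))
  if (is.unsorted(scan_times, strictly = TRUE)) {
    stop("scan times must be strictly increasing", call. = FALSE)
  }
  structure(list(sample_id = sample_id,
                 scan_times = as.numeric(scan_times),
                 centroids = centroids,
                 ms_level = as.integer(ms_level)),
            class = "ats_scan_map")
}

#' @export
print.ats_scan_map <- function(x, ...) {
  cat(sprintf("<ats_scan_map> %s: %d MS%d scans, %.3f-%.3f min\n",
              x$sample_id, length(x$scan_times), x$ms_level,
              min(x$scan_times), max(x$scan_times)))
  invisible(x)
}

#' Read a centroided mzML file into a scan map
#'
#' Loads all scans of the requested MS level from a centroided mzML file.
#' Retention times are converted to minutes. Scans stored out of time order
#' are re-sorted when `resort = TRUE` (the default), otherwise rejected.
#'
#' @param path Path to an mzML file.
#' @param ms_level MS level to keep (the workflow operates on MS1).
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param resort Re-sort scans by retention time if stored out of order.
#' @return An `ats_scan_map`: sample id, scan times (minutes), and one
#'   centroid matrix (`mz`, `intensity`) per scan.
#' @export
read_scan_map <- function(path, ms_level = 1L, sample_id = NULL,
                          resort = TRUE) {
  if (!file.exists(path)) stop("mzML file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]+$", "", basename(path))
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("cannot read mzML file ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  keep <- which(hdr$msLevel == ms_level)
  if (!length(keep)) {
    stop("no MS", ms_level, " scans in ", path, call. = FALSE)
  }
  if (any(!is.na(hdr$centroided[keep]) & !hdr$centroided[keep])) {
    stop("profile-mode scans in ", path,
         "; the workflow requires centroided data", call. = FALSE)
  }
  rt_min <- hdr$retentionTime[keep] / 60
  pks <- mzR::peaks(ms, keep)
  if (is.matrix(pks)) pks <- list(pks)
  pks <- lapply(pks, function(m) {
    m <- m[m[, 2] > 0, , drop = FALSE]
    colnames(m) <- c("mz", "intensity")
    m
  })
  ord <- order(rt_min)
  if (is.unsorted(rt_min, strictly = TRUE)) {
    if (!resort) stop("scans out of retention-time order in ", path,
                      call. = FALSE)
    rt_min <- rt_min[ord]
    pks <- pks[ord]
  }
  new_scan_map(sample_id, rt_min, pks, ms_level)
}

# ---- EIC -------------------------------------------------------------------

new_eic <- function(rt, intensity, analyte_id = NA_character_,
                    sample_id = NA_character_, mz_target = NA_real_,
                    tol = NA_real_, tol_unit = "ppm",
                    window = c(NA_real_, NA_real_),
                    is_background = FALSE, is_smoothed = FALSE) {
  out <- tibble(rt = as.numeric(rt), intensity = as.numeric(intensity))
  attr(out, "analyte_id") <- analyte_id
  attr(out, "sample_id") <- sample_id
  attr(out, "mz_target") <- mz_target
  attr(out, "tol") <- tol
  attr(out, "tol_unit") <- tol_unit
  attr(out, "window") <- window
  attr(out, "is_background") <- is_background
  attr(out, "is_smoothed") <- is_smoothed
  class(out) <- c("ats_eic", class(out))
  out
}

is_smoothed <- function(eic) isTRUE(attr(eic, "is_smoothed"))

#' @export
print.ats_eic <- function(x, ...) {
  cat(sprintf(
    "<ats_eic> %s / %s  m/z %.4f (+/- %g %s)  %d points%s%s\n",
    attr(x, "analyte_id"), attr(x, "sample_id"), attr(x, "mz_target"),
    attr(x, "tol"), attr(x, "tol_unit"), nrow(x),
    if (isTRUE(attr(x, "is_background"))) "  [background]" else "",
    if (is_smoothed(x)) "  [smoothed]" else ""))
  NextMethod()
}

mz_halfwidth <- function(mz, tol, unit) {
  if (identical(unit, "ppm")) mz * tol / 1e6 else tol
}

#' Extract an ion chromatogram from a scan map
#'
#' For every scan whose time falls inside `window`, sums the intensities of
#' all centroids within `mz` plus/minus the tolerance. Scans with no
#' matching centroid contribute an explicit zero so point counts reflect the
#' acquisition rate.
#'
#' @param scan_map An `ats_scan_map` from [read_scan_map()].
#' @param mz Target m/z.
#' @param tol Extraction tolerance (> 0).
#' @param window Retention-time window `c(lo, hi)` in minutes; defaults to
#'   the full scan range.
#' @param tol_unit `"ppm"` or `"Da"`.
#' @param analyte_id,is_background Metadata carried on the result.
#' @return An `ats_eic` tibble with columns `rt` and `intensity`.
#' @export
extract_eic <- function(scan_map, mz, tol, window = NULL, tol_unit = "ppm",
                        analyte_id = NA_character_, is_background = FALSE) {
  stopifnot(inherits(scan_map, "ats_scan_map"), tol > 0)
  if (is.null(window)) window <- range(scan_map$scan_times)
  idx <- which(scan_map$scan_times >= window[1] &
                 scan_map$scan_times <= window[2])
  dm <- mz_halfwidth(mz, tol, tol_unit)
  if (!length(idx)) {
    return(new_eic(numeric(0), numeric(0), analyte_id, scan_map$sample_id,
                   mz, tol, tol_unit, window, is_background))
  }
  ints <- vapply(scan_map$centroids[idx], function(m) {
    if (!nrow(m)) return(0)
    sel <- abs(m[, "mz"] - mz) <= dm
    if (any(sel)) sum(m[sel, "intensity"]) else 0
  }, numeric(1))
  new_eic(scan_map$scan_times[idx], ints, analyte_id, scan_map$sample_id,
          mz, tol, tol_unit, window, is_background)
}

#' Widen a search window for background estimation
#'
#' The background EIC spans the analyte search window widened symmetrically
#' by `factor`, then clipped to the acquisition range when supplied.
#'
#' @param window `c(lo, hi)` minutes.
#' @param factor Widening factor (>= 1); the output width is `factor` times
#'   the input width, centred on the input.
#' @param scan_range Optional acquisition range to clip against.
#' @return `c(lo, hi)` of the widened window.
#' @export
background_window <- function(window, factor, scan_range = NULL) {
  stopifnot(length(window) == 2, window[2] >= window[1], factor >= 1)
  half_extra <- (factor - 1) * diff(window) / 2
  out <- c(window[1] - half_extra, window[2] + half_extra)
  if (!is.null(scan_range)) {
    out <- c(max(out[1], scan_range[1]), min(out[2], scan_range[2]))
  }
  out
}

#' Smooth an EIC for shape analysis
#'
#' Produces a denser, smoothed copy of the trace used only by the
#' shape-dependent steps (SAX encoding, shape comparison). Quantitative
#' steps (height, area, baseline) always consume the raw trace; feeding a
#' smoothed EIC to [integrate_area()] is an error.
#'
#' The default scheme interpolates linearly onto a grid of half the native
#' scan spacing and applies a 5-point centred moving average.
#'
#' @param eic A raw `ats_eic`.
#' @param params [ats_params()].
#' @return A smoothed `ats_eic` tagged `is_smoothed`.
#' @export
smooth_for_shape <- function(eic, params = ats_params()) {
  stopifnot(inherits(eic, "ats_eic"))
  if (nrow(eic) < 3) {
    warning("fewer than 3 points; returning trace unsmoothed")
    return(eic)
  }
  rt <- eic$rt
  y <- eic$intensity
  if (identical(params$smoothing, "interp_ma")) {
    step <- median(diff(rt)) / 2
    grid <- seq(rt[1], rt[length(rt)], by = step)
    y <- approx(rt, y, xout = grid)$y
    rt <- grid
  }
  ys <- moving_average(y, 5)
  out <- new_eic(rt, ys, attr(eic, "analyte_id"), attr(eic, "sample_id"),
                 attr(eic, "mz_target"), attr(eic, "tol"),
                 attr(eic, "tol_unit"), attr(eic, "window"),
                 attr(eic, "is_background"), is_smoothed = TRUE)
  out
}

moving_average <- function(y, k) {
  n <- length(y)
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(y[lo:hi])
  }, numeric(1))
}

#' Integrate a peak area by the trapezoidal rule
#'
#' @param eic A raw (never smoothed) `ats_eic`.
#' @param start_idx,end_idx 1-based indices bounding the integration,
#'   inclusive.
#' @return Area in intensity * minutes.
#' @export
integrate_area <- function(eic, start_idx, end_idx) {
  stopifnot(inherits(eic, "ats_eic"))
  if (is_smoothed(eic)) {
    stop("integrate_area() must not consume a smoothed EIC", call. = FALSE)
  }
  n <- nrow(eic)
  stopifnot(start_idx >= 1, end_idx <= n, start_idx < end_idx)
  i <- start_idx:end_idx
  sum(diff(eic$rt[i]) * (head(eic$intensity[i], -1) +
                           tail(eic$intensity[i], -1)) / 2)
}

#' Data density of a trace
#'
#' The workflow's density unit: the number of raw points within a 0.1-minute
#' window. Computed as the median, over all points used as anchors, of the
#' count of points falling in the half-open window `[t, t + 0.1)`.
#'
#' @param eic An `ats_eic` with at least 2 points.
#' @param width Window width in minutes.
#' @return Median points per `width` minutes.
#' @export
data_density <- function(eic, width = 0.1) {
  stopifnot(nrow(eic) >= 2)
  rt <- eic$rt
  counts <- vapply(rt, function(t0) sum(rt >= t0 & rt < t0 + width),
                   numeric(1))
  median(counts)
}
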