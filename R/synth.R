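# Seeded synthetic-batch generator: chromatograms with Gaussian or
# exponentially modified Gaussian (tailed) peaks, additive baseline and
# noise, optional zigzag interference and co-eluting isomers, linear
# response-concentration relations with optional saturation and blank
# contamination, and per-sample / per-compound retention-time shifts. Every
# other layer of the package is exercised against its ground truth.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# exponentially modified Gaussian, numerically stable, scaled so the
# maximum equals `height`; tau = 0 gives a plain Gaussian
emg_profile <- function(t, apex, height, sigma, tau = 0) {
  if (tau <= 0) return(height * exp(-(t - apex)^2 / (2 * sigma^2)))
  k <- sigma / tau
  z <- (k - (t - apex) / sigma) / sqrt(2)
  logf <- 0.5 * k^2 - (t - apex) / tau + log(2) +
    pnorm(z * sqrt(2), lower.tail = FALSE, log.p = TRUE)
  f <- exp(logf)
  m <- max(f)
  if (!is.finite(m) || m <= 0) return(rep(0, length(t)))
  height * f / m
}

#' Simulate one chromatographic acquisition
#'
#' Builds scan times and centroid lists for a set of planted peaks on a
#' noisy baseline. Each m/z channel receives one centroid per scan with
#' intensity = sum of its peak profiles + baseline + Gaussian noise
#' (truncated at zero). Zigzag interference replaces a channel's trace in a
#' time segment with alternating spikes.
#'
#' @param peaks Tibble with columns `mz`, `apex_rt` (min), `height`
#'   (counts), `sigma` (min), and optionally `asymmetry` (EMG tail constant
#'   as a multiple of `sigma`; 0 = symmetric). May have zero rows.
#' @param rt_range Acquisition range `c(lo, hi)` in minutes.
#' @param spacing Scan spacing in minutes.
#' @param baseline Additive baseline level (counts).
#' @param noise_sd Standard deviation of the additive noise.
#' @param channels m/z channels that always emit a centroid (defaults to
#'   the peak channels); channels without peaks carry baseline + noise.
#' @param zigzag Optional tibble with `mz`, `start`, `end`, `high`:
#'   alternating `high`/near-baseline spikes over `[start, end]`.
#' @param mz_jitter_ppm Optional ppm-scale jitter on written centroid m/z.
#' @param sample_id Identifier for the resulting scan map.
#' @param seed Integer seed (`NULL` = use the current RNG state).
#' @return An `ats_scan_map`.
#' @export
make_chromatogram <- function(peaks, rt_range = c(0, 12), spacing = 0.02,
                              baseline = 0, noise_sd = 0, channels = NULL,
                              zigzag = NULL, mz_jitter_ppm = 0,
                              sample_id = "synthetic", seed = NULL) {
  with_seed(seed, {
    times <- seq(rt_range[1], rt_range[2], by = spacing)
    if (is.null(channels)) channels <- unique(peaks$mz)
    channels <- sort(unique(channels))
    if (!length(channels)) stop("no m/z channels to simulate", call. = FALSE)
    if (!"asymmetry" %in% names(peaks) && nrow(peaks)) peaks$asymmetry <- 0
    traces <- matrix(0, nrow = length(times), ncol = length(channels))
    for (i in seq_len(nrow(peaks))) {
      j <- match(peaks$mz[i], channels)
      traces[, j] <- traces[, j] +
        emg_profile(times, peaks$apex_rt[i], peaks$height[i],
                    peaks$sigma[i], peaks$asymmetry[i] * peaks$sigma[i])
    }
    traces <- traces + baseline
    if (noise_sd > 0) {
      traces <- traces + matrix(rnorm(length(traces), 0, noise_sd),
                                nrow = nrow(traces))
    }
    if (!is.null(zigzag) && nrow(zigzag)) {
      for (i in seq_len(nrow(zigzag))) {
        j <- match(zigzag$mz[i], channels)
        if (is.na(j)) next
        seg <- which(times >= zigzag$start[i] & times <= zigzag$end[i])
        alt <- rep(c(TRUE, FALSE), length.out = length(seg))
        traces[seg[alt], j] <- zigzag$high[i] +
          if (noise_sd > 0) rnorm(sum(alt), 0, noise_sd) else 0
        traces[seg[!alt], j] <- baseline +
          if (noise_sd > 0) abs(rnorm(sum(!alt), 0, noise_sd / 2)) else 0
      }
    }
    traces[traces < 0] <- 0
    centroids <- lapply(seq_along(times), function(s) {
      mzv <- channels
      if (mz_jitter_ppm > 0) {
        mzv <- mzv * (1 + rnorm(length(mzv), 0, mz_jitter_ppm / 1e6))
      }
      keep <- traces[s, ] > 0
      cbind(mz = mzv[keep], intensity = traces[s, keep])
    })
    new_scan_map(sample_id, times, centroids)
  })
}

#' Write a scan map to a centroided mzML file
#'
#' @param scan_map An `ats_scan_map`.
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(scan_map, path) {
  stopifnot(inherits(scan_map, "ats_scan_map"))
  n <- length(scan_map$scan_times)
  pks <- lapply(scan_map$centroids, function(m) {
    m <- m[, c("mz", "intensity"), drop = FALSE]
    storage.mode(m) <- "double"
    m
  })
  counts <- vapply(pks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = scan_map$ms_level, polarity = 1L, peaksCount = counts,
    totIonCurrent = vapply(pks, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = scan_map$scan_times * 60,
    basePeakMZ = vapply(pks, function(m)
      if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pks, function(m)
      if (nrow(m)) max(m[, 2]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pks, function(m) if (nrow(m)) min(m[, 1]) else 0,
                   numeric(1)),
    highMZ = vapply(pks, function(m) if (nrow(m)) max(m[, 1]) else 0,
                    numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Specify a synthetic screening batch
#'
#' Collects the design of a full batch: targets, internal standards, sample
#' groups, response model, shifts, and noise regime. Defaults emulate an
#' LC-HRMS screening batch: calibration from 0.1 to 1000 ng/mL, Gaussian
#' peaks of a few seconds width on a low noisy baseline.
#'
#' @param targets Tibble with `analyte_id`, `mz`, `expected_rt`, and
#'   optionally `sensitivity` (height counts per ng/mL), `sigma`,
#'   `asymmetry`, `conf_mz`, `conf_ratio`, `is_id`, `blank_level` (blank
#'   contamination, ng/mL), `sat_height` (saturation ceiling, counts).
#' @param is_list Tibble with `is_id`, `mz`, `expected_rt`, and optionally
#'   `height` (spiked response).
#' @param cal_levels Nominal calibration concentrations (ng/mL).
#' @param n_blanks,n_samples,n_references Group sizes.
#' @param reference_conc Concentration of the constant references.
#' @param include_is_only Include an IS-only control sample.
#' @param sample_conc Matrix (analyte x sample) or named generator function
#'   of true sample concentrations; default draws half absent, half
#'   log-uniform inside the calibration range.
#' @param global_shift_min Batch-wide retention-time displacement of the
#'   acquired data (minutes).
#' @param sample_shift_sd Per-sample shift jitter (SD, minutes).
#' @param rt_jitter_sd Independent per-peak retention-time jitter (SD,
#'   minutes) applied to every planted analyte and IS peak.
#' @param compound_shift_range Per-compound data shift range `c(lo, hi)`
#'   (minutes), e.g. `c(-1.1, -0.9)`.
#' @param response_cv Multiplicative response noise (fractional SD).
#' @param rt_range,spacing,baseline,noise_sd Acquisition geometry and noise.
#' @param mode `"LC"` or `"GC"`.
#' @param seed Integer seed.
#' @return A list of class `ats_batch_spec`.
#' @export
batch_spec <- function(targets, is_list,
                       cal_levels = c(0.1, 0.5, 1, 5, 10, 50, 100, 1000),
                       n_blanks = 3, n_samples = 8, n_references = 3,
                       reference_conc = 100, include_is_only = TRUE,
                       sample_conc = NULL, global_shift_min = 0,
                       sample_shift_sd = 0, rt_jitter_sd = 0,
                       compound_shift_range = c(0, 0), response_cv = 0,
                       rt_range = c(0, 12), spacing = 0.02, baseline = 20,
                       noise_sd = 3, mode = "LC", seed = 1L) {
  defaults <- list(sensitivity = 500, sigma = 0.04, asymmetry = 0,
                   conf_mz = NA_real_, conf_ratio = NA_real_,
                   is_id = is_list$is_id[1], blank_level = 0,
                   sat_height = Inf)
  for (k in names(defaults)) {
    if (!k %in% names(targets)) targets[[k]] <- defaults[[k]]
  }
  if (!"height" %in% names(is_list)) is_list$height <- 5e4
  if (!"sigma" %in% names(is_list)) is_list$sigma <- 0.04
  structure(as.list(environment())[names(formals(batch_spec))],
            class = "ats_batch_spec")
}

#' Generate a synthetic batch with ground truth
#'
#' Realises a [batch_spec()]: one scan map per sample (solvent blanks,
#' calibration levels, constant references, optional IS-only control, and
#' unknown samples) plus machine-readable truth tables.
#'
#' @param spec An `ats_batch_spec`.
#' @param write_dir Optional directory; when given, every sample is written
#'   as centroided mzML and the manifest gains a `file` column.
#' @return List of class `ats_batch`: `scan_maps` (named list), `manifest`
#'   (sample_id, group, conc, file), `targets`, `is_list`, `truth`
#'   (analyte x sample: present, conc, true apex/height), and the
#'   generating `ats_batch_spec`.
#' @export
make_batch <- function(spec, write_dir = NULL) {
  stopifnot(inherits(spec, "ats_batch_spec"))
  with_seed(spec$seed, make_batch_impl(spec, write_dir))
}

make_batch_impl <- function(spec, write_dir) {
  tg <- spec$targets
  n_t <- nrow(tg)
  manifest <- dplyr::bind_rows(
    tibble(sample_id = sprintf("blank_%02d", seq_len(spec$n_blanks)),
           group = "blank", conc = NA_real_),
    tibble(sample_id = sprintf("cal_%02d", seq_along(spec$cal_levels)),
           group = "calibration", conc = spec$cal_levels),
    tibble(sample_id = sprintf("ref_%02d", seq_len(spec$n_references)),
           group = "reference", conc = spec$reference_conc),
    if (spec$include_is_only) {
      tibble(sample_id = "is_only_01", group = "is_only", conc = NA_real_)
    },
    tibble(sample_id = sprintf("sample_%02d", seq_len(spec$n_samples)),
           group = "sample", conc = NA_real_)
  )

  # true concentrations in unknown samples: half absent, half log-uniform
  # inside the central calibration range
  smp_ids <- manifest$sample_id[manifest$group == "sample"]
  if (is.null(spec$sample_conc)) {
    conc_mat <- matrix(0, n_t, length(smp_ids),
                       dimnames = list(tg$analyte_id, smp_ids))
    rng <- range(spec$cal_levels)
    lo <- min(rng[1] * 10, rng[2] / 2)
    hi <- max(rng[1] * 10, rng[2] / 2)
    for (i in seq_len(n_t)) {
      present <- sample(c(TRUE, FALSE), length(smp_ids), replace = TRUE)
      conc_mat[i, present] <- 10^runif(sum(present), log10(lo), log10(hi))
    }
  } else {
    conc_mat <- spec$sample_conc
  }

  comp_shift <- runif(n_t, spec$compound_shift_range[1],
                      spec$compound_shift_range[2])
  samp_shift <- setNames(
    spec$global_shift_min +
      if (spec$sample_shift_sd > 0) {
        rnorm(nrow(manifest), 0, spec$sample_shift_sd)
      } else rep(0, nrow(manifest)),
    manifest$sample_id)

  channels <- sort(unique(c(tg$mz, tg$conf_mz[!is.na(tg$conf_mz)],
                            spec$is_list$mz)))
  resp_height <- function(i, conc) {
    h <- tg$sensitivity[i] * conc
    if (is.finite(tg$sat_height[i])) {
      h <- tg$sat_height[i] * (1 - exp(-h / tg$sat_height[i]))
    }
    h
  }

  scan_maps <- list()
  truth <- list()
  for (s in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[s]
    grp <- manifest$group[s]
    shift_s <- samp_shift[[sid]]
    rows <- list()
    for (i in seq_len(n_t)) {
      conc <- switch(grp,
        blank = tg$blank_level[i],
        calibration = manifest$conc[s],
        reference = manifest$conc[s],
        matrix_qc = manifest$conc[s],
        is_only = 0,
        sample = conc_mat[tg$analyte_id[i], sid])
      if (conc <= 0) {
        truth[[length(truth) + 1]] <- tibble(
          analyte_id = tg$analyte_id[i], sample_id = sid, group = grp,
          present = FALSE, conc = 0, true_apex_rt = NA_real_,
          true_height = NA_real_)
        next
      }
      h <- resp_height(i, conc)
      if (spec$response_cv > 0) h <- h * exp(rnorm(1, 0, spec$response_cv))
      apex <- tg$expected_rt[i] + comp_shift[i] + shift_s +
        if (spec$rt_jitter_sd > 0) rnorm(1, 0, spec$rt_jitter_sd) else 0
      rows[[length(rows) + 1]] <- tibble(
        mz = tg$mz[i], apex_rt = apex, height = h, sigma = tg$sigma[i],
        asymmetry = tg$asymmetry[i])
      if (!is.na(tg$conf_mz[i])) {
        rows[[length(rows) + 1]] <- tibble(
          mz = tg$conf_mz[i], apex_rt = apex, height = h * tg$conf_ratio[i],
          sigma = tg$sigma[i], asymmetry = tg$asymmetry[i])
      }
      truth[[length(truth) + 1]] <- tibble(
        analyte_id = tg$analyte_id[i], sample_id = sid, group = grp,
        present = TRUE, conc = conc, true_apex_rt = apex, true_height = h)
    }
    is_tbl <- spec$is_list
    for (k in seq_len(nrow(is_tbl))) {
      h <- is_tbl$height[k]
      if (spec$response_cv > 0) h <- h * exp(rnorm(1, 0, spec$response_cv))
      apex_is <- is_tbl$expected_rt[k] + shift_s +
        if (spec$rt_jitter_sd > 0) rnorm(1, 0, spec$rt_jitter_sd) else 0
      rows[[length(rows) + 1]] <- tibble(
        mz = is_tbl$mz[k], apex_rt = apex_is,
        height = h, sigma = is_tbl$sigma[k], asymmetry = 0)
    }
    pk <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble(mz = numeric(0), apex_rt = numeric(0), height = numeric(0),
             sigma = numeric(0), asymmetry = numeric(0))
    scan_maps[[sid]] <- make_chromatogram(
      pk, rt_range = spec$rt_range, spacing = spec$spacing,
      baseline = spec$baseline, noise_sd = spec$noise_sd,
      channels = channels, sample_id = sid, seed = NULL)
  }

  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$file <- file.path(write_dir,
                               paste0(manifest$sample_id, ".mzML"))
    for (s in seq_len(nrow(manifest))) {
      write_mzml(scan_maps[[manifest$sample_id[s]]], manifest$file[s])
    }
  }
  structure(list(scan_maps = scan_maps, manifest = manifest,
                 targets = tg, is_list = spec$is_list,
                 truth = dplyr::bind_rows(truth), spec = spec),
            class = "ats_batch")
}

#' @export
print.ats_batch <- function(x, ...) {
  cat(sprintf("<ats_batch> %d samples (%s), %d targets, %d IS\n",
              nrow(x$manifest),
              paste(sprintf("%d %s", table(x$manifest$group),
                            names(table(x$manifest$group))), collapse = ", "),
              nrow(x$targets), nrow(x$is_list)))
  invisible(x)
}
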