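# Batch orchestration: the six-step workflow over a sample manifest and a
# target list. Steps: (A) EIC generation and peak detection wherever raw
# data is touched; (B) batch-global shift from internal standards; (C)
# reference-guided peak-list annotation and intensity-dependent shift
# check; (D) per-sample IS shifts; (E) screening of every analyte in every
# sample; (F) blank masking, matrix correction, reference validation,
# calibration, concentrations, and recoveries.

sample_groups <- c("blank", "reference", "calibration", "matrix_qc",
                   "is_only", "sample")

check_manifest <- function(manifest) {
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!manifest$group %in% sample_groups)
  if (length(bad)) {
    stop("manifest row ", bad[1], ": unknown group \"",
         manifest$group[bad[1]], "\"", call. = FALSE)
  }
  bad <- which(manifest$group == "calibration" & !is.finite(manifest$conc))
  if (length(bad)) {
    stop("manifest row ", bad[1],
         ": calibration sample without a nominal concentration",
         call. = FALSE)
  }
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicated sample_id in manifest", call. = FALSE)
  }
  invisible(manifest)
}

check_targets <- function(targets, is_list) {
  need <- c("analyte_id", "mz", "expected_rt")
  miss <- setdiff(need, names(targets))
  if (length(miss)) {
    stop("target list lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(targets$analyte_id)) {
    stop("duplicated analyte_id in target list", call. = FALSE)
  }
  for (k in c("conf_mz", "conf_ratio")) {
    if (!k %in% names(targets)) targets[[k]] <- NA_real_
  }
  if (!"is_id" %in% names(targets)) targets$is_id <- NA_character_
  unresolved <- setdiff(stats::na.omit(unique(targets$is_id)),
                        is_list$is_id)
  if (length(unresolved)) {
    stop("assigned internal standard(s) not in the IS list: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  targets
}

# analyte EIC + background EIC + baseline stats for one channel of a sample
channel_stats <- function(scan_map, mz, window, params) {
  scan_range <- range(scan_map$scan_times)
  bw <- background_window(window, params$background_extension_factor,
                          scan_range)
  bg <- extract_eic(scan_map, mz, params$mz_tol_default, bw,
                    params$mz_tol_unit, is_background = TRUE)
  # the analyte EIC is the in-window slice of the background trace
  keep <- bg$rt >= max(window[1], scan_range[1]) &
    bg$rt <= min(window[2], scan_range[2])
  eic <- new_eic(bg$rt[keep], bg$intensity[keep],
                 analyte_id = attr(bg, "analyte_id"),
                 sample_id = scan_map$sample_id, mz_target = mz,
                 tol = params$mz_tol_default, tol_unit = params$mz_tol_unit,
                 window = window)
  stats <- if (nrow(bg) >= 10) estimate_baseline(bg, params) else
    estimate_baseline_fallback()
  list(eic = eic, bg = bg, stats = stats)
}

estimate_baseline_fallback <- function() {
  structure(list(baseline = 0, noise = 0, quantile_used = NA_real_,
                 lod = 0, loq = 0,
                 triggers = c(zigzag_exceeded = FALSE, rmse_exceeded = FALSE,
                              ratio_too_low = FALSE),
                 degenerate = TRUE),
            class = "ats_baseline")
}

find_channel_peak <- function(scan_map, mz, expected_rt, window, params,
                              cutoff = 0) {
  ch <- channel_stats(scan_map, mz, window, params)
  pks <- find_peaks(ch$eic, ch$stats, params)
  # the in-trace cutoff keeps sub-fragment local maxima from outcompeting
  # the real peak when the baseline is so quiet that the LOD degenerates
  cutoff <- max(cutoff, params$minimum_cutoff_intensity_factor *
                  (if (nrow(pks)) max(pks$height) else 0))
  pks <- split_merged(pks, ch$eic, cutoff_height = cutoff)
  list(peak = select_peak(pks, expected_rt, window, cutoff, ch$stats$lod),
       stats = ch$stats, eic = ch$eic)
}

#' Run the full screening and quantification workflow on a batch
#'
#' @param manifest Tibble with `sample_id`, `group` (one of blank,
#'   reference, calibration, matrix_qc, is_only, sample), `conc` (nominal,
#'   for calibration/reference rows), and `file` (mzML path) unless
#'   `scan_maps` is supplied.
#' @param targets Target list: `analyte_id`, `mz`, `expected_rt`, optional
#'   `conf_mz`, `conf_ratio`, `is_id`.
#' @param is_list Internal standards: `is_id`, `mz`, `expected_rt`.
#' @param params [ats_params()].
#' @param scan_maps Optional named list of `ats_scan_map` keyed by
#'   sample_id (bypasses mzML reading; [make_batch()] output plugs in
#'   directly).
#' @param mode `"LC"` or `"GC"` (retention-time window floor).
#' @param allow_check Quantify CHECK hits (supervised re-evaluation).
#' @return An `ats_result` list: `hits`, `responses`, `quant`,
#'   `qualitative` (analyte x sample status matrix), `calibrations`,
#'   `consensus`, `shifts`, and `log`.
#' @export
ats_run <- function(manifest, targets, is_list, params = ats_params(),
                    scan_maps = NULL, mode = c("LC", "GC"),
                    allow_check = FALSE) {
  mode <- match.arg(mode)
  manifest <- check_manifest(manifest)
  targets <- check_targets(targets, is_list)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (is.null(scan_maps)) {
    if (!"file" %in% names(manifest)) {
      stop("manifest needs a `file` column when scan_maps are not supplied",
           call. = FALSE)
    }
    scan_maps <- lapply(seq_len(nrow(manifest)), function(i) {
      read_scan_map(manifest$file[i], sample_id = manifest$sample_id[i])
    })
    names(scan_maps) <- manifest$sample_id
  }
  floor_hw <- if (mode == "LC") params$rt_window_floor_lc else
    params$rt_window_floor_gc

  # ---- B: global shift from internal standards ----------------------------
  is_apex <- list()   # [[is_id]][[sample_id]] apex rt
  is_peak <- list()   # [[is_id \r sample_id]] full peak row (reused in F)
  shifts <- list()
  for (k in seq_len(nrow(is_list))) {
    isid <- is_list$is_id[k]
    is_apex[[isid]] <- list()
    for (sid in manifest$sample_id) {
      full <- range(scan_maps[[sid]]$scan_times)
      fp <- find_channel_peak(scan_maps[[sid]], is_list$mz[k],
                              is_list$expected_rt[k], full, params)
      if (!is.null(fp$peak)) {
        is_apex[[isid]][[sid]] <- fp$peak$apex_rt[1]
        is_peak[[paste(isid, sid, sep = "\r")]] <- fp$peak
        shifts[[length(shifts) + 1]] <- tibble(
          is_id = isid, sample_id = sid,
          shift = fp$peak$apex_rt[1] - is_list$expected_rt[k])
      }
    }
  }
  is_shift_tbl <- if (length(shifts)) dplyr::bind_rows(shifts) else
    tibble(is_id = character(0), sample_id = character(0),
           shift = numeric(0))
  gs <- global_shift(is_shift_tbl$shift, mode, params)
  note("global shift %.4f min over %d IS observations; half-width %.4f min",
       gs$mean_shift, gs$n, gs$halfwidth)

  # per-sample IS displacement relative to the IS consensus over the
  # annotation samples (so the global component is not counted twice)
  ref_ids <- manifest$sample_id[manifest$group %in%
                                  c("reference", "calibration")]
  is_consensus_rt <- lapply(is_apex, function(per_sample) {
    anchor <- unlist(per_sample[intersect(names(per_sample), ref_ids)])
    if (!length(anchor)) anchor <- unlist(per_sample)
    if (length(anchor)) median(anchor) else NA_real_
  })
  per_sample_is <- function(isid, sid) {
    a <- is_apex[[isid]][[sid]]
    ref <- is_consensus_rt[[isid]]
    if (is.null(a) || !length(a) || !is.finite(ref)) {
      list(shift = 0, fallback = TRUE)
    } else list(shift = a - ref, fallback = FALSE)
  }

  # ---- C: reference-guided annotation -------------------------------------
  cal_ids <- manifest$sample_id[manifest$group == "calibration"]
  is_only_ids <- manifest$sample_id[manifest$group == "is_only"]
  have_refs <- length(ref_ids) > 0
  if (!have_refs) {
    warning("no reference or calibration samples: screening-only mode ",
            "against the target list")
  }
  consensus <- list()
  trends <- list()
  for (i in seq_len(nrow(targets))) {
    aid <- targets$analyte_id[i]
    centre <- targets$expected_rt[i] + gs$mean_shift
    win <- c(centre - gs$halfwidth, centre + gs$halfwidth)
    ref_peaks <- list()
    ref_eics <- list()
    cal_rows <- list()
    for (sid in ref_ids) {
      fp <- find_channel_peak(scan_maps[[sid]], targets$mz[i], centre, win,
                              params)
      if (!is.null(fp$peak)) {
        ref_peaks[[sid]] <- fp$peak
        ref_eics[[sid]] <- fp$eic
        if (sid %in% cal_ids) {
          cal_rows[[sid]] <- tibble(
            conc = manifest$conc[manifest$sample_id == sid],
            apex_rt = fp$peak$apex_rt[1], height = fp$peak$height[1])
        }
      }
    }
    cal_tbl <- if (length(cal_rows)) dplyr::bind_rows(cal_rows) else NULL
    hb <- if (!is.null(cal_tbl)) setNames(cal_tbl$height, cal_tbl$conc)
    cons <- build_consensus(ref_peaks, ref_eics, aid, hb, params)
    if (is.null(cons) && have_refs) {
      note("analyte %s: no reference peak found; unscreenable", aid)
    }
    if (is.null(cons) && !have_refs) {
      # screening-only fallback: trust the target list
      cons <- structure(list(
        analyte_id = aid, expected_rt = centre,
        left_width = floor_hw / 2, right_width = floor_hw / 2,
        rt_range = win, shape = NULL, max_ref_height = Inf,
        height_by_level = NULL, n_references = 0L),
        class = "ats_consensus")
      cons$max_ref_height <- 0
    }
    consensus[[aid]] <- cons
    if (!is.null(cons) && !is.null(cal_tbl) && nrow(cal_tbl) >= 3) {
      ctrl <- NULL
      if (length(is_only_ids)) {
        ch <- channel_stats(scan_maps[[is_only_ids[1]]], targets$mz[i],
                            cons$rt_range, params)
        pk <- find_peaks(ch$eic, ch$stats, params)
        ctrl <- pk[pk$height >= ch$stats$lod, , drop = FALSE]
      }
      tr <- intensity_shift(cal_tbl, ctrl, params)
      if (!is.null(tr)) {
        note("analyte %s: intensity-dependent shift %.4f min/log10",
             aid, tr$slope)
        trends[[aid]] <- tr
      }
    }
  }

  # ---- E: screen every analyte in every sample ----------------------------
  hit_rows <- list()
  for (i in seq_len(nrow(targets))) {
    aid <- targets$analyte_id[i]
    cons <- consensus[[aid]]
    if (is.null(cons)) {
      hit_rows[[length(hit_rows) + 1]] <- tibble(
        analyte_id = aid, sample_id = manifest$sample_id,
        status = "NOT_DETECTED", apex_rt = NA_real_, height = NA_real_,
        area = NA_real_, n_points = NA_integer_, applied_shift = NA_real_,
        check_reasons = "no_consensus")
      next
    }
    isid <- targets$is_id[i]
    for (sid in manifest$sample_id) {
      iss <- if (!is.na(isid)) per_sample_is(isid, sid) else
        list(shift = 0, fallback = TRUE)
      win <- c(cons$rt_range[1] - gs$halfwidth,
               cons$rt_range[2] + gs$halfwidth)
      ch <- channel_stats(scan_maps[[sid]], targets$mz[i], win, params)
      conf <- NULL
      if (!is.na(targets$conf_mz[i])) {
        cch <- channel_stats(scan_maps[[sid]], targets$conf_mz[i], win,
                             params)
        conf <- list(eics = list(cch$eic), ratios = targets$conf_ratio[i],
                     stats = list(cch$stats))
      }
      hit_rows[[length(hit_rows) + 1]] <- screen_sample(
        ch$eic, ch$stats, cons, gs$halfwidth, floor_hw,
        is_shift = iss$shift, trend = trends[[aid]], conf = conf,
        params = params, analyte_id = aid, sample_id = sid)
    }
  }
  hits <- dplyr::bind_rows(hit_rows)

  # ---- F: responses, masking, calibration, quantification -----------------
  resp_col <- params$response_type
  get_is_resp <- function(isid, sid) {
    if (is.na(isid)) return(NA_real_)
    pk <- is_peak[[paste(isid, sid, sep = "\r")]]
    if (is.null(pk)) NA_real_ else pk[[resp_col]][1]
  }

  responses <- dplyr::left_join(
    hits,
    dplyr::select(manifest, "sample_id", "group", "conc"),
    by = "sample_id")
  responses$response <- dplyr::coalesce(responses[[resp_col]], 0)
  responses$is_response <- mapply(function(aid, sid) {
    get_is_resp(targets$is_id[match(aid, targets$analyte_id)], sid)
  }, responses$analyte_id, responses$sample_id)
  responses$adjusted <- responses$response
  responses$masked <- FALSE
  responses$rr <- NA_real_

  out_rows <- list()
  cal_fits <- list()
  for (i in seq_len(nrow(targets))) {
    aid <- targets$analyte_id[i]
    r <- responses[responses$analyte_id == aid, , drop = FALSE]
    blanks <- r$response[r$group == "blank" & r$status != "NOT_DETECTED"]
    all_blanks <- r$response[r$group == "blank"]
    bm <- if (length(all_blanks)) {
      blank_mask(r$response, all_blanks, params)
    } else tibble(response = r$response, adjusted = r$response,
                  masked = FALSE)
    r$adjusted <- bm$adjusted
    r$masked <- bm$masked & r$status != "NOT_DETECTED"
    if (any(r$masked)) {
      note("analyte %s: %d sample(s) masked by background", aid,
           sum(r$masked))
    }
    r$rr <- ifelse(is.finite(r$is_response) & r$is_response > 0,
                   r$adjusted / r$is_response, r$adjusted)
    if (all(!is.finite(r$is_response) | r$is_response <= 0)) {
      note("analyte %s: no internal-standard response; raw responses used",
           aid)
    }
    mqc <- r$rr[r$group == "matrix_qc" & r$status == "DETECTED"]
    solv <- r$rr[r$group == "reference" & r$status == "DETECTED"]
    mc <- if (length(mqc)) matrix_correction(mqc, solv) else 1
    r$rr_corrected <- r$rr * ifelse(r$group %in% c("sample", "matrix_qc"),
                                    mc, 1)

    cal <- r[r$group == "calibration" & !r$masked &
               r$status %in% c("DETECTED", if (allow_check) "CHECK"), ,
             drop = FALSE]
    fit <- if (nrow(cal) >= params$min_cal_points) {
      fit_calibration(tibble(conc = cal$conc, rr = cal$rr_corrected),
                      params)
    }
    cal_fits[[aid]] <- fit

    refs <- r[r$group == "reference" & r$status == "DETECTED" & !r$masked, ,
              drop = FALSE]
    valid_ref <- if (nrow(refs)) {
      refs$rr_corrected[validate_references(refs$rr_corrected, params)]
    } else numeric(0)

    for (j in seq_len(nrow(r))) {
      if (!r$group[j] %in% c("sample", "matrix_qc")) next
      q <- quantify_sample(r$status[j], r$rr_corrected[j], fit,
                           masked = r$masked[j], allow_check = allow_check)
      rec <- if (length(valid_ref) && r$status[j] == "DETECTED" &&
                 !r$masked[j]) {
        recovery(r$rr_corrected[j], valid_ref)
      } else NA_real_
      out_rows[[length(out_rows) + 1]] <- tibble(
        analyte_id = aid, sample_id = r$sample_id[j],
        response = r$response[j], response_ratio = r$rr_corrected[j],
        concentration = q$concentration, exclusion = q$exclusion,
        recovery = rec)
    }
    responses$adjusted[responses$analyte_id == aid] <- r$adjusted
    responses$masked[responses$analyte_id == aid] <- r$masked
    responses$rr[responses$analyte_id == aid] <- r$rr_corrected
  }
  quant <- if (length(out_rows)) dplyr::bind_rows(out_rows) else
    tibble(analyte_id = character(0), sample_id = character(0),
           response = numeric(0), response_ratio = numeric(0),
           concentration = numeric(0), exclusion = character(0),
           recovery = numeric(0))

  qual <- dplyr::mutate(
    dplyr::select(responses, "analyte_id", "sample_id", "status", "masked"),
    call = dplyr::case_when(
      masked ~ "masked_by_background",
      status == "DETECTED" ~ "TRUE",
      TRUE ~ "FALSE"))
  qual_matrix <- tidyr::pivot_wider(
    dplyr::select(qual, "analyte_id", "sample_id", "call"),
    names_from = "sample_id", values_from = "call")

  structure(list(
    hits = hits,
    responses = dplyr::select(responses, "analyte_id", "sample_id",
                              "group", "status", "response", "is_response",
                              "adjusted", "masked", "rr"),
    quant = quant, qualitative = qual_matrix,
    calibrations = cal_fits, consensus = consensus,
    shifts = list(global = gs, is_shifts = is_shift_tbl,
                  trends = trends),
    params = params, log = log_lines),
    class = "ats_result")
}

#' @export
print.ats_result <- function(x, ...) {
  st <- table(x$hits$status)
  cat("<ats_result>\n")
  cat(sprintf("  %d analyte x sample decisions: %s\n", nrow(x$hits),
              paste(sprintf("%d %s", st, names(st)), collapse = ", ")))
  ncal <- sum(!vapply(x$calibrations, is.null, logical(1)))
  cat(sprintf("  %d/%d analytes with an accepted calibration\n", ncal,
              length(x$calibrations)))
  cat(sprintf("  global shift %.3f min (half-width %.3f)\n",
              x$shifts$global$mean_shift, x$shifts$global$halfwidth))
  invisible(x)
}
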