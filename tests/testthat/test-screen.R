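mk_cons <- function(expected_rt = 5, width = 0.1, max_h = 1000) {
  structure(list(analyte_id = "a", expected_rt = expected_rt,
                 left_width = width / 2, right_width = width / 2,
                 rt_range = expected_rt + c(-1, 1) * width,
                 shape = NULL, max_ref_height = max_h,
                 height_by_level = NULL, n_references = 3L),
            class = "ats_consensus")
}

mk_peak <- function(apex = 5, h = 1000, width = 0.1, n = 12L) {
  tibble::tibble(start_idx = 1L, apex_idx = 2L, end_idx = 3L,
                 start_rt = apex - width / 2, apex_rt = apex,
                 end_rt = apex + width / 2, height = h, area = h * width,
                 n_points = n, plateau_truncated = FALSE,
                 split_enforced = FALSE)
}

test_that("confirming-ion logic: confirmed / not expected / missing", {
  p <- ats_params()
  qp <- mk_peak(h = 1000)
  # conf trace carrying a matching peak at ratio 0.48
  conf_sm <- make_chromatogram(
    tibble::tibble(mz = 200, apex_rt = 5, height = 480, sigma = 0.03,
                   asymmetry = 0),
    rt_range = c(4, 6), spacing = 0.01, baseline = 5)
  conf_eic <- extract_eic(conf_sm, 200, 5)
  st <- flat_stats(5, 5)  # lod 20
  expect_equal(confirmers_check(qp, list(conf_eic), 0.5, list(st), p),
               "confirmed")
  # expected conf intensity below its LOD -> not demandable
  qp_small <- mk_peak(h = 200)
  st_hi <- flat_stats(100, 10)   # lod 130 > expected 100
  expect_equal(confirmers_check(qp_small, list(conf_eic), 0.5, list(st_hi),
                                p), "not_expected")
  # expected above LOD but trace empty -> missing
  empty <- extract_eic(make_chromatogram(
    tibble::tibble(mz = 200, apex_rt = 5, height = 0, sigma = 0.03,
                   asymmetry = 0)[0, ],
    rt_range = c(4, 6), spacing = 0.01, baseline = 5, channels = 200), 200, 5)
  expect_equal(confirmers_check(qp, list(empty), 0.5, list(st), p),
               "missing")
  # measured ratio outside 20% tolerance -> missing
  expect_equal(confirmers_check(mk_peak(h = 2000), list(conf_eic), 0.5,
                                list(st), p), "missing")
  # no confirming ions defined -> vacuously confirmed
  expect_equal(confirmers_check(qp, list(), numeric(0), list(), p),
               "confirmed")
})

test_that("screening statuses: DETECTED, CHECK gates, NOT_DETECTED", {
  p <- ats_params()
  cons <- mk_cons(5, width = 0.25, max_h = 1000)
  st <- flat_stats(10, 1)
  # clean peak, all gates pass
  e <- gaussian_eic(apex = 5, height = 1000, sigma = 0.05, baseline = 10)
  hit <- screen_sample(e, st, cons, halfwidth = 0.5, floor_hw = 0.5,
                       analyte_id = "a", sample_id = "s")
  expect_equal(hit$status, "DETECTED")
  expect_gt(hit$area, 0)
  expect_lt(abs(hit$apex_rt - 5), 0.02)
  # absent analyte
  e0 <- gaussian_eic(apex = 5, height = 0, baseline = 10)
  hit0 <- screen_sample(e0, st, cons, 0.5, 0.5, analyte_id = "a",
                        sample_id = "s")
  expect_equal(hit0$status, "NOT_DETECTED")
  # narrow spike: few points -> CHECK with the area still integrated
  e5 <- gaussian_eic(apex = 5, height = 1000, sigma = 0.007,
                     baseline = 10, spacing = 0.01)
  hit5 <- screen_sample(e5, st, cons, 0.5, 0.5, analyte_id = "a",
                        sample_id = "s")
  expect_equal(hit5$status, "CHECK")
  expect_match(hit5$check_reasons, "too_few_points")
  expect_gt(hit5$area, 0)
  # apex far from the expectation -> shift gate
  e_far <- gaussian_eic(apex = 5.45, height = 1000, sigma = 0.05,
                        baseline = 10)
  hit_far <- screen_sample(e_far, st, mk_cons(5, width = 0.12), 0.5, 0.1,
                           analyte_id = "a", sample_id = "s")
  expect_equal(hit_far$status, "CHECK")
  expect_match(hit_far$check_reasons, "shift_out_of_range")
})

test_that("raising min_peak_points never converts CHECK into DETECTED", {
  st <- flat_stats(10, 1)
  cons <- mk_cons(5, width = 0.25)
  e <- gaussian_eic(apex = 5, height = 1000, sigma = 0.03, baseline = 10,
                    spacing = 0.01)
  statuses <- vapply(c(5, 7, 11, 15, 25), function(mpp) {
    screen_sample(e, st, cons, 0.5, 0.5,
                  params = ats_params(min_peak_points = mpp),
                  analyte_id = "a", sample_id = "s")$status
  }, character(1))
  ranks <- c(DETECTED = 1, CHECK = 2, NOT_DETECTED = 3)
  expect_true(all(diff(ranks[statuses]) >= 0))
})

test_that("a valid peak at the uncorrected RT overrides the IS shift", {
  st <- flat_stats(10, 1)
  cons <- mk_cons(5, width = 0.25)
  e <- gaussian_eic(apex = 5, height = 1000, sigma = 0.05, baseline = 10,
                    spacing = 0.01)
  # a wrong IS shift of +0.4 min would displace the window; the peak sits
  # exactly at the consensus RT, so the shift is ignored
  hit <- screen_sample(e, st, cons, halfwidth = 0.5, floor_hw = 0.5,
                       is_shift = 0.4, analyte_id = "a", sample_id = "s")
  expect_equal(hit$status, "DETECTED")
  expect_equal(hit$applied_shift, 0)
  expect_lt(abs(hit$apex_rt - 5), 0.02)
})

test_that("screening is deterministic", {
  st <- flat_stats(10, 1)
  cons <- mk_cons(5, width = 0.25)
  e <- gaussian_eic(apex = 5.02, height = 800, sigma = 0.05, baseline = 10,
                    noise_sd = 20, seed = 7)
  h1 <- screen_sample(e, st, cons, 0.5, 0.5, analyte_id = "a",
                      sample_id = "s")
  h2 <- screen_sample(e, st, cons, 0.5, 0.5, analyte_id = "a",
                      sample_id = "s")
  expect_identical(h1, h2)
})

test_that("MINDIST gate applies only away from the expected retention time", {
  # consensus shape from a clean Gaussian
  ge <- gaussian_eic(apex = 5, height = 1000, sigma = 0.05, baseline = 0)
  pks <- find_peaks(ge, flat_stats(0))
  top <- pks[which.max(pks$height), ]
  cons <- mk_cons(5, width = 0.2)
  cons$shape <- encode_sax(ge$intensity[top$start_idx:top$end_idx], 7)
  st <- flat_stats(5, 10)   # LOD 35 keeps noise fragments out
  # an in-window peak well away from the expected RT (no significant
  # intensity near 5.0, so the tolerance bypass does not apply); a
  # right-triangle ramp differs from the Gaussian consensus by more than
  # one SAX bin at matched positions, so MINDIST exceeds a strict ceiling
  rt <- seq(3, 7, 0.01)
  y <- rep(0, length(rt))
  ramp <- rt >= 4.50 & rt <= 4.70
  y[ramp] <- 800 * (rt[ramp] - 4.50) / 0.20
  y[rt > 4.70 & rt <= 4.73] <- c(500, 200, 50)
  off <- eic_from(rt, y)
  strict <- ats_params(use_MINDIST = TRUE, mindist_ceiling = 0.01)
  hit <- screen_sample(off, st, cons, 0.5, 0.5, params = strict,
                       analyte_id = "a", sample_id = "s")
  expect_equal(hit$status, "CHECK")
  expect_match(hit$check_reasons, "shape_mismatch")
  # same trace with the gate off never reports a shape reason
  hit2 <- screen_sample(off, st, cons, 0.5, 0.5,
                        params = ats_params(use_MINDIST = FALSE),
                        analyte_id = "a", sample_id = "s")
  expect_false(grepl("shape_mismatch", hit2$check_reasons))
  # a matching peak at the expected RT passes even with the gate on
  lenient <- ats_params(use_MINDIST = TRUE, mindist_ceiling = 2)
  hit3 <- screen_sample(ge, st, cons, 0.5, 0.5, params = lenient,
                        analyte_id = "a", sample_id = "s")
  expect_equal(hit3$status, "DETECTED")
})
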