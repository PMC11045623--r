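test_that("blank masking subtracts and masks per the one-third / 3x rules", {
  p <- ats_params()
  # blanks all clean -> no masking
  out <- blank_mask(c(400, 150), c(0, 0, 0), p)
  expect_equal(out$adjusted, c(400, 150))
  expect_false(any(out$masked))
  # 2/3 blanks contaminated, mean 73.3
  out <- blank_mask(c(400, 150), c(100, 120, 0), p)
  bm <- mean(c(100, 120, 0))
  expect_equal(out$adjusted[1], 400 - bm)
  expect_false(out$masked[1])     # 400 > 3 x 73.3
  expect_true(out$masked[2])      # 150 <= 220
  # exactly 1/3 does not trigger (rule is strictly more than a third)
  out <- blank_mask(c(400), c(100, 0, 0), p)
  expect_equal(out$adjusted, 400)
  # idempotence: masking already-masked data changes nothing
  once <- blank_mask(c(400, 150), c(100, 120, 0), p)
  twice <- blank_mask(once$adjusted, c(0, 0, 0), p)
  expect_equal(twice$adjusted, once$adjusted)
  expect_warning(blank_mask(c(1), numeric(0), p), "no solvent blanks")
})

test_that("matrix correction inverts median suppression", {
  expect_equal(matrix_correction(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(matrix_correction(c(0.5, 0.5), c(1, 1)), 2)
  set.seed(41)
  m <- 0.7 * exp(rnorm(4, 0, 0.05))
  s <- 1.0 * exp(rnorm(4, 0, 0.05))
  expect_lt(abs(matrix_correction(m, s) - 1 / 0.7) / (1 / 0.7), 0.10)
  expect_message(f <- matrix_correction(numeric(0), c(1)), "absent")
  expect_equal(f, 1)
})

test_that("reference validation uses 1.5 IQR fences", {
  expect_true(all(validate_references(c(100, 102, 98))))
  keep <- validate_references(c(100, 102, 98, 250))
  # hand computation: Q1 99.5, Q3 139, IQR 39.5 -> fence 198.25
  expect_equal(keep, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(validate_references(rep(5, 4))))
  expect_warning(validate_references(c(1, 2)), "fewer than 3")
})

test_that("quantification error is the median absolute percent deviation", {
  fit <- list(slope = 1, intercept = 0)
  expect_equal(error_quantification(fit, c(10, 20), c(10, 20)), 0)
  # predictions 9 and 11 for actual 10 -> both 10%
  expect_equal(error_quantification(fit, c(10, 10), c(9, 11)), 10)
  # median of {10, 5, 0}
  expect_equal(error_quantification(fit, c(10, 20, 40), c(9, 21, 40)), 5)
  expect_error(error_quantification(list(slope = 0, intercept = 0),
                                    c(1), c(1)), "slope")
})

test_that("an exact line is fitted with zero error and full retention", {
  lv <- tibble::tibble(conc = c(0.1, 0.5, 1, 5, 10, 100),
                       rr = 2 * c(0.1, 0.5, 1, 5, 10, 100))
  fit <- fit_calibration(lv)
  expect_s3_class(fit, "ats_calfit")
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$error_quant, 0, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(nrow(fit$included_levels), 6)
  # round trip at every level, for whatever variant won
  expect_equal(atscreen:::invert_calibration(fit, lv$rr), lv$conc,
               tolerance = 1e-9)
})

test_that("all six variants invert exactly on noiseless lines", {
  conc <- c(0.5, 1, 5, 10, 50, 100)
  for (origin in c(TRUE, FALSE)) {
    for (w in c("none", "x", "1/x")) {
      rr <- 3 * conc + if (origin) 0 else 0.4
      f <- atscreen:::fit_one_variant(conc, rr, origin, w)
      expect_equal((rr - f$intercept) / f$slope, conc, tolerance = 1e-8)
      expect_equal(f$error, 0, tolerance = 1e-7)
    }
  }
})

test_that("8-level lines with 5% noise: slope bias < 2%, error and R2 in spec", {
  # the top level dominates every weighting, so a single draw's slope can
  # deviate by the full noise SD; the recovery claim is statistical
  set.seed(59)
  conc <- c(0.1, 0.5, 1, 5, 10, 50, 100, 1000)
  devs <- replicate(100, {
    rr <- 2 * conc * exp(rnorm(8, 0, 0.05))
    fit <- fit_calibration(tibble::tibble(conc = conc, rr = rr))
    expect_false(is.null(fit))
    expect_lt(fit$error_quant, 30)
    expect_gte(fit$r2, 0.95)
    expect_lt(error_quantification(fit, fit$included_levels$conc,
                                   fit$included_levels$rr), 10)
    (fit$slope - 2) / 2
  })
  expect_lt(abs(mean(devs)), 0.02)        # slope bias
  expect_lt(median(abs(devs)), 0.05)      # typical single-batch deviation
})

test_that("a gross outlier at the top level is trimmed by Cook's distance", {
  conc <- c(0.1, 0.5, 1, 5, 10, 50, 100, 1000)
  rr <- 2 * conc
  rr[8] <- rr[8] * 10           # 10x high at the top level
  fit <- fit_calibration(tibble::tibble(conc = conc, rr = rr))
  expect_false(is.null(fit))
  expect_true(1000 %in% fit$removed_levels$conc)
  expect_gte(nrow(fit$included_levels), 4)
  expect_lt(abs(fit$slope - 2) / 2, 0.02)
})

test_that("trimming never drops below the minimum level count", {
  set.seed(61)
  conc <- c(1, 5, 10, 50, 100)
  rr <- 2 * conc * exp(rnorm(5, 0, 0.3))   # ugly but fittable
  fit <- fit_calibration(tibble::tibble(conc = conc, rr = rr),
                         ats_params(min_r2 = 0, max_error_quant = 10))
  if (!is.null(fit)) expect_gte(nrow(fit$included_levels), 4)
  expect_null(fit_calibration(tibble::tibble(conc = c(1, 2, 3),
                                             rr = c(2, 4, 6))))
})

test_that("sample quantification respects status, masking, and range cutoffs", {
  lv <- tibble::tibble(conc = c(1, 5, 10, 100), rr = 2 * c(1, 5, 10, 100))
  fit <- fit_calibration(lv)
  # ratio exactly at a retained level returns that level's concentration
  q <- quantify_sample("DETECTED", 2 * 5, fit)
  expect_equal(q$concentration, 5, tolerance = 1e-9)
  expect_equal(q$exclusion, "none")
  # below the lowest retained ratio
  q <- quantify_sample("DETECTED", 0.5, fit)
  expect_equal(q$exclusion, "below_calibration")
  expect_true(is.na(q$concentration))
  # above the highest retained ratio
  q <- quantify_sample("DETECTED", 500, fit)
  expect_equal(q$exclusion, "above_calibration")
  # CHECK without override is excluded; with override it quantifies
  q <- quantify_sample("CHECK", 2 * 5, fit)
  expect_equal(q$exclusion, "check_status")
  q <- quantify_sample("CHECK", 2 * 5, fit, allow_check = TRUE)
  expect_equal(q$concentration, 5, tolerance = 1e-9)
  # masking wins over everything
  q <- quantify_sample("DETECTED", 2 * 5, fit, masked = TRUE)
  expect_equal(q$exclusion, "masked_by_background")
  # no calibration
  q <- quantify_sample("DETECTED", 2, NULL)
  expect_equal(q$exclusion, "no_calibration")
})

test_that("recovery is the percentage of the valid reference median", {
  expect_equal(recovery(1.0, c(1.0, 1.1, 0.9)), 100)
  expect_equal(recovery(0.5, c(1.0, 1.1, 0.9)), 50)
  expect_equal(recovery(0.8, c(1.0, 1.1, 0.9)), 80)
  expect_warning(r <- recovery(1, numeric(0)), "no valid")
  expect_true(is.na(r))
})

test_that("tidy and glance summarise calibration fits", {
  lv <- tibble::tibble(conc = c(1, 5, 10, 100), rr = 2 * c(1, 5, 10, 100))
  fit <- fit_calibration(lv)
  td <- tidy(fit)
  expect_true("conc" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n_levels, 4L)
  expect_equal(gl$slope, 2, tolerance = 1e-9)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
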