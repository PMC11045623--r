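two_gauss_eic <- function(sep_sigma, h1 = 1000, h2 = 1000, sigma = 0.05,
                          baseline = 10, spacing = 0.01, noise_sd = 0,
                          seed = NULL) {
  sm <- make_chromatogram(
    tibble::tibble(mz = 100, apex_rt = c(5, 5 + sep_sigma * sigma),
                   height = c(h1, h2), sigma = sigma, asymmetry = 0),
    rt_range = c(3, 8), spacing = spacing, baseline = baseline,
    noise_sd = noise_sd, seed = seed)
  extract_eic(sm, 100, 5)
}

test_that("a single Gaussian yields one peak at the brute-force argmax", {
  e <- gaussian_eic(baseline = 10)
  pks <- find_peaks(e, flat_stats(10))
  big <- pks[pks$height > 100, ]
  expect_equal(nrow(big), 1)
  expect_equal(big$apex_idx, which.max(e$intensity))
  expect_equal(big$height, max(e$intensity))
})

test_that("a 20% shoulder bump is absorbed into one peak", {
  # 25-point trace, density 10: descending flank with a 2-point +20% bump
  y <- c(5, 6, 8, 12, 30, 80, 200, 420, 700, 900, 1000, 950, 800, 600,
         420, 300, 360, 360, 210, 120, 60, 30, 12, 8, 5)
  e <- eic_from(seq(0, by = 0.01, length.out = 25), y)
  pks <- find_peaks(e, flat_stats(5))
  big <- pks[pks$height > 100, ]
  expect_equal(nrow(big), 1)
  expect_equal(big$apex_idx, 11)
  expect_lte(big$start_idx, 5)
  expect_gte(big$end_idx, 21)   # spans the bump at points 17-18
})

test_that("well-separated Gaussians give two non-overlapping peaks", {
  e <- two_gauss_eic(10)
  pks <- find_peaks(e, flat_stats(10))
  big <- pks[pks$height > 100, ]
  expect_equal(nrow(big), 2)
  big <- dplyr::arrange(big, apex_rt)
  expect_lt(big$end_idx[1], big$start_idx[2])
})

test_that("merged Gaussians 3 sigma apart split at the brute-force valley", {
  # (two equal Gaussians closer than ~2 sigma sum to a unimodal envelope:
  # there is no valley; 3 sigma is the closest clearly merged bimodal case)
  e <- two_gauss_eic(3)
  pks <- find_peaks(e, flat_stats(10))
  pks <- split_merged(pks, e)
  big <- dplyr::arrange(pks[pks$height > 100, ], apex_rt)
  expect_equal(nrow(big), 2)
  expect_true(any(big$split_enforced))
  # brute-force valley between the true apexes
  i1 <- which.min(abs(e$rt - 5))
  i2 <- which.min(abs(e$rt - 5.15))
  valley <- (i1:i2)[which.min(e$intensity[i1:i2])]
  expect_lte(abs(big$end_idx[1] - valley), 1)
  expect_lte(abs(big$start_idx[2] - valley), 1)
})

test_that("splitting preserves total area and the index partition", {
  e <- two_gauss_eic(3)
  pks <- find_peaks(e, flat_stats(10))
  before <- dplyr::arrange(pks[pks$height > 100, ], apex_rt)
  parent_area <- integrate_area(e, min(before$start_idx),
                                max(before$end_idx))
  after <- dplyr::arrange(split_merged(pks, e)[pks$height > 100, ], apex_rt)
  # children tile the parent: shared boundary, no gaps
  expect_equal(after$end_idx[1], after$start_idx[2])
  cell <- diff(e$rt)[after$end_idx[1]] *
    max(e$intensity[after$start_idx[2] + c(-1, 0, 1)])
  expect_lt(abs(sum(after$area) - parent_area), cell + 1e-9)
  # every index belongs to at most one peak (the split point is the shared
  # fence between the two)
  idx <- unlist(mapply(function(s, ge) s:ge, after$start_idx, after$end_idx))
  expect_lte(max(table(idx)), 2)
  expect_equal(sum(table(idx) == 2), 1)
})

test_that("disjoint peaks pass the splitter unchanged", {
  e <- two_gauss_eic(10)
  pks <- find_peaks(e, flat_stats(10))
  # cutoff as in the pipeline: sub-cutoff fragments bypass the splitter
  out <- split_merged(pks, e, cutoff_height = 100)
  expect_equal(out$start_idx, pks$start_idx)
  expect_equal(out$end_idx, pks$end_idx)
  expect_false(any(out$split_enforced))
})

test_that("a 10:1 closely eluting isomer pair is split and both apexes kept", {
  # same m/z, small RT gap, strongly unequal heights (fragrance-isomer case)
  e <- two_gauss_eic(4, h1 = 5000, h2 = 500)
  pks <- split_merged(find_peaks(e, flat_stats(10)), e)
  big <- dplyr::arrange(pks[pks$height > 100, ], apex_rt)
  expect_equal(nrow(big), 2)
  expect_lt(abs(big$apex_rt[1] - 5), 0.015)
  expect_lt(abs(big$apex_rt[2] - 5.2), 0.015)
  expect_gt(big$height[1] / big$height[2], 5)
})

test_that("peaks below the cutoff bypass the splitting function", {
  e <- two_gauss_eic(3, h1 = 400, h2 = 400)
  pks <- find_peaks(e, flat_stats(10))
  out <- split_merged(pks, e, cutoff_height = 1000)
  expect_false(any(out$split_enforced))
})

test_that("consensus peaks take medians and span the widest reference", {
  mk <- function(apex, lw, rw, h) {
    tibble::tibble(start_idx = 1L, apex_idx = 2L, end_idx = 3L,
                   start_rt = apex - lw, apex_rt = apex, end_rt = apex + rw,
                   height = h, area = h, n_points = 3L,
                   plateau_truncated = FALSE, split_enforced = FALSE)
  }
  refs <- list(r1 = mk(10.00, 0.10, 0.10, 100),
               r2 = mk(10.02, 0.12, 0.12, 900),
               r3 = mk(10.04, 0.30, 0.30, 500))
  cons <- build_consensus(refs, NULL, "a")
  expect_equal(cons$expected_rt, 10.02)
  expect_equal(cons$left_width, 0.12)
  expect_equal(cons$rt_range, c(10.04 - 0.30, 10.04 + 0.30))
  expect_true(cons$rt_range[1] <= cons$expected_rt &
                cons$expected_rt <= cons$rt_range[2])
  expect_equal(cons$max_ref_height, 900)
  # identical references -> consensus equals any one
  same <- list(r1 = mk(8, 0.1, 0.1, 50), r2 = mk(8, 0.1, 0.1, 50),
               r3 = mk(8, 0.1, 0.1, 50))
  c2 <- build_consensus(same, NULL, "b")
  expect_equal(c2$expected_rt, 8)
  expect_equal(c2$left_width, 0.1)
  # no references -> unscreenable
  expect_null(build_consensus(list(), NULL, "c"))
})

test_that("select_peak honours window, cutoff, LOD, and the tie rule", {
  mk <- function(apex, h) {
    tibble::tibble(start_idx = 1L, apex_idx = 2L, end_idx = 3L,
                   start_rt = apex - 0.05, apex_rt = apex,
                   end_rt = apex + 0.05, height = h, area = h,
                   n_points = 10L, plateau_truncated = FALSE,
                   split_enforced = FALSE)
  }
  pks <- dplyr::bind_rows(mk(9.9, 100), mk(10.1, 500))
  # equidistant -> taller wins
  got <- select_peak(pks, 10.0, c(9, 11), cutoff_height = 0, lod = 0)
  expect_equal(got$height, 500)
  # nearest wins when distances differ
  got <- select_peak(pks, 9.92, c(9, 11), 0, 0)
  expect_equal(got$height, 100)
  # all below cutoff -> none
  expect_null(select_peak(pks, 10, c(9, 11), cutoff_height = 1000, lod = 0))
  # below LOD -> none
  expect_null(select_peak(pks, 10, c(9, 11), 0, lod = 1000))
  # outside window -> none
  expect_null(select_peak(pks, 10, c(11, 12), 0, 0))
})

test_that("walker apex recovery is stable over a noisy synthetic suite", {
  set.seed(99)
  ok <- 0L
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    h <- 10^runif(1, 2.5, 4)
    e <- gaussian_eic(apex = runif(1, 4, 6), height = h, sigma = 0.05,
                      baseline = 10, noise_sd = h / 20, spacing = 0.01)
    st <- estimate_baseline(e)
    pks <- find_peaks(e, st)
    top <- pks[which.max(pks$height), ]
    if (abs(top$apex_idx - which.max(e$intensity)) <= 1) ok <- ok + 1L
  }
  expect_equal(ok, n_rep)
})
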