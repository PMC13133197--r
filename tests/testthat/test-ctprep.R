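# HU preprocessing: resampling, segmentation, histogram fit, porosity laws.

test_that("isotropic resampling preserves constants and reproduces linear ramps", {
  vc <- image_volume(array(7, c(6, 6, 6)), c(0.5, 0.5, 1))
  expect_lt(max(abs(resample_isotropic(vc, 0.5)$values - 7)), 1e-10)

  # cubic B-splines reproduce polynomials up to degree 3; check a linear
  # ramp away from the mirror boundary
  arr <- array(0, c(6, 6, 40))
  zs <- (0:39) * 0.6
  for (k in 1:40) arr[, , k] <- 3 + 2 * zs[k]
  rv <- resample_isotropic(image_volume(arr, c(0.326, 0.326, 0.6)), 0.326)
  zz <- voxel_coords(rv)[[3]]
  interior <- zz >= 7.5 & zz <= max(zs) - 7.5
  expect_lt(max(abs(rv$values[3, 3, interior] - (3 + 2 * zz[interior]))), 1e-6)

  # output spacing and physical extent
  expect_equal(rv$spacing, rep(0.326, 3))
  expect_lt(abs(dim(rv$values)[3] * 0.326 - 40 * 0.6), 0.6)
  expect_error(resample_isotropic(image_volume(array(c(1, NA, 1, 1, 1, 1, 1, 1),
                                                     c(2, 2, 2))), 0.5),
               "non-finite")
})

test_that("threshold segmentation covers trivial and disjoint cases", {
  v <- image_volume(array(rnorm(4^3), c(4, 4, 4)))
  expect_true(all(segment_by_threshold(v, -Inf, Inf)))
  lo <- segment_by_threshold(v, -Inf, 0)
  hi <- segment_by_threshold(v, 0, Inf)
  expect_false(any(lo & hi))
  expect_true(all(lo | hi))
  expect_warning(segment_by_threshold(v, 99, 100), "empty")
})

test_that("cortical threshold segmentation recovers the phantom shell", {
  ph <- oriented_phantom()
  sp <- ph$truth$spec
  cort_true <- ph$truth$labels == 1L
  seg <- segment_by_threshold(ph$volume, sp$hu_cortical_range[1] - 150, Inf,
                              morphology_ops = list(c("close", 1)))
  recovered <- sum(seg & cort_true) / sum(cort_true)
  expect_gte(recovered, 0.95)
})

test_that("HU threshold fit matches the normal quantile and the empirical oracle", {
  set.seed(1)
  x <- rnorm(20000)
  fit <- fit_hu_threshold(x, family = "normal", cdf_level = 0.98)
  expect_lt(abs(fit$threshold - qnorm(0.98)), 0.05)  # 2.054 as n grows
  fit50 <- fit_hu_threshold(x, family = "normal", cdf_level = 0.5)
  expect_lt(abs(fit50$threshold - median(x)), 0.05)

  # empirical fallback equals the sort-based 98th percentile
  xb <- c(rnorm(5000, -3), rnorm(5000, 3))   # bimodal
  fe <- fit_hu_threshold(xb, family = "empirical", cdf_level = 0.98)
  expect_equal(fe$threshold, as.numeric(quantile(xb, 0.98, type = 7)))
  expect_true(fe$fallback)

  # auto picks the best log-likelihood family on skewed data
  xs <- rgamma(5000, shape = 3, rate = 1)
  fa <- fit_hu_threshold(xs, family = "auto")
  expect_true(fa$family %in% c("skewnormal", "gamma"))
  expect_error(fit_hu_threshold(rnorm(50)), "at least 100")
})

test_that("porosity laws hit their anchors and derived values", {
  cal <- calibration_params(hu_mode_trab = 200, hu_min_trab = 50,
                            hu_threshold = 700, hu_min_cort = 300)
  expect_equal(as.numeric(hu_to_porosity_trabecular(200, cal)), 0.85)
  expect_equal(as.numeric(hu_to_porosity_trabecular(50, cal)), 0.92)
  expect_equal(as.numeric(hu_to_porosity_trabecular(125, cal)), 0.885)
  expect_equal(as.numeric(hu_to_porosity_cortical(700, cal)), 0)
  expect_equal(as.numeric(hu_to_porosity_cortical(300, cal)), 0.5)
  expect_equal(as.numeric(hu_to_porosity_cortical(500, cal)), 0.25)
  # above-threshold HU is dense cortical bone: zero porosity
  expect_equal(as.numeric(hu_to_porosity_cortical(2000, cal)), 0)
})

test_that("porosity is non-increasing in HU and matches a brute-force oracle", {
  cal <- calibration_params(hu_mode_trab = 180, hu_min_trab = 40,
                            hu_threshold = 650, hu_min_cort = 250)
  hu <- seq(-100, 2000, by = 10)
  pt <- hu_to_porosity_trabecular(hu, cal)
  pc <- hu_to_porosity_cortical(hu, cal)
  expect_true(all(diff(pt) <= 1e-12))
  expect_true(all(diff(pc) <= 1e-12))
  expect_true(all(pt >= 0 & pt <= 1))
  expect_true(all(pc >= 0 & pc <= cal$phi_max_cort))

  set.seed(2)
  grid <- array(runif(16^3, -200, 1500), c(16, 16, 16))
  ref_t <- pmin(pmax(cal$phi_mode_trab + (grid - cal$hu_mode_trab) *
                       (cal$phi_max_trab - cal$phi_mode_trab) /
                       (cal$hu_min_trab - cal$hu_mode_trab), 0), 1)
  ref_c <- pmin(pmax((cal$hu_threshold - grid) /
                       (cal$hu_threshold - cal$hu_min_cort) * cal$phi_max_cort,
                     0), cal$phi_max_cort)
  expect_equal(as.numeric(hu_to_porosity_trabecular(grid, cal)),
               as.numeric(ref_t), tolerance = 1e-15)
  expect_equal(as.numeric(hu_to_porosity_cortical(grid, cal)),
               as.numeric(ref_c), tolerance = 1e-15)
})

test_that("porosity field recovers phantom truth to machine precision", {
  ph <- oriented_phantom()
  tr <- ph$truth
  pf <- porosity_field(ph$volume, tr$labels == 1L, tr$labels == 2L,
                       tr$calibration)
  inside <- tr$labels > 0
  expect_equal(pf$porosity[inside], tr$porosity_truth[inside],
               tolerance = 1e-12)
  expect_true(all(pf$tissue[tr$labels == 1L] == 1L))
})
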