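# Synthetic vertebra phantom: determinism, histogram shape, anisotropy
# response, two-body scene geometry.

test_that("fixed seed gives bit-identical volumes", {
  sp <- small_phantom_spec(seed = 21)
  a <- make_vertebra_phantom(sp)
  b <- make_vertebra_phantom(sp)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("degenerate half-axes are rejected", {
  expect_error(phantom_spec(body_half_axes = c(0, 10, 10)), "degenerate")
  expect_error(phantom_spec(texture_anisotropy = 1), "texture_anisotropy")
  expect_error(phantom_spec(hu_cortical_range = c(100, 150),
                            hu_trabecular_mode = 200), "above")
})

test_that("trabecular HU histogram is unimodal with the mode on target", {
  ph <- oriented_phantom()
  hu <- ph$volume$values[ph$truth$labels == 2L]
  dd <- density(hu, n = 512)
  mode_hu <- dd$x[which.max(dd$y)]
  target <- ph$truth$spec$hu_trabecular_mode
  expect_lt(abs(mode_hu - target) / target, 0.02)
  peaks <- which(diff(sign(diff(dd$y))) == -2) + 1
  expect_equal(sum(dd$y[peaks] > 0.1 * max(dd$y)), 1)  # single major mode
  # high-HU tail: right tail heavier than left
  expect_gt(quantile(hu, 0.99) - mode_hu, mode_hu - quantile(hu, 0.01) - 1e-9)
})

test_that("phantom porosity truth lies in [0,1] and directions are unit", {
  ph <- oriented_phantom()
  tr <- ph$truth
  phi <- tr$porosity_truth[tr$labels > 0]
  expect_true(all(phi >= 0 & phi <= 1))
  expect_equal(rowSums(tr$direction_truth^2),
               rep(1, nrow(tr$direction_truth)), tolerance = 1e-12)
})

test_that("downstream anisotropy is monotone in the texture anisotropy", {
  medians <- vapply(c(0.1, 0.4, 0.7), function(a) {
    ph <- make_vertebra_phantom(small_phantom_spec(anisotropy = a, seed = 11))
    f <- gradient_structure_tensor(ph$volume, ph$truth$labels == 2L)
    ok <- !f$isotropic[f$voxel_index]
    median(f$DA[f$voxel_index][ok])
  }, numeric(1))
  expect_true(all(diff(medians) > 0))
})

test_that("two-vertebra scene has the requested gap and disjoint bodies", {
  sp <- small_phantom_spec(seed = 13)
  sc <- make_two_vertebra_scene(sp, gap_mm = 9)
  lab <- sc$truth$labels
  bid <- sc$truth$body_id
  zc <- voxel_coords(sc$volume)[[3]]
  # column through the axis: gap between the two bodies
  d <- dim(lab)
  col <- lab[ceiling(d[1] / 2), ceiling(d[2] / 2), ]
  inz <- range(which(col > 0))
  gaps <- which(col == 0 & seq_along(col) > inz[1] & seq_along(col) < inz[2])
  gap_mm <- (max(gaps) - min(gaps) + 1) * sc$volume$spacing[3]
  expect_lt(abs(gap_mm - 9), sc$volume$spacing[3] + 1e-9)
  # bodies disjoint even at a one-slice gap
  sc2 <- make_two_vertebra_scene(sp, gap_mm = 0.6)
  expect_true(all(sc2$truth$body_id %in% 0:2))
  z1 <- range(voxel_coords(sc2$volume)[[3]][apply(sc2$truth$body_id == 1,
                                                  3, any)])
  z2 <- range(voxel_coords(sc2$volume)[[3]][apply(sc2$truth$body_id == 2,
                                                  3, any)])
  expect_lt(z1[2], z2[1])
  expect_error(make_two_vertebra_scene(sp, gap_mm = 0), "overlap")
})

test_that("a mirrored texture direction mirrors nothing in the labels", {
  spa <- small_phantom_spec(seed = 17)
  spb <- small_phantom_spec(seed = 17)
  spb$texture_direction <- -spb$texture_direction
  a <- make_vertebra_phantom(spa)
  b <- make_vertebra_phantom(spb)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("phantom config round-trips through YAML", {
  sp <- small_phantom_spec(seed = 5)
  path <- tempfile(fileext = ".yaml")
  write_phantom_config(sp, path)
  y <- yaml::read_yaml(path)
  expect_equal(y$seed, 5)
  expect_equal(y$body_half_axes, sp$body_half_axes)
})
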