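# Gradient structure tensor: analytic fields, boundary rule, oracle
# equivalence, invariances.

test_that("constant intensity gives a zero tensor flagged isotropic", {
  v <- image_volume(array(5, c(12, 12, 12)))
  lab <- array(TRUE, c(12, 12, 12))
  f <- gradient_structure_tensor(v, lab)
  expect_true(all(f$isotropic[f$voxel_index]))
  expect_true(all(f$lambda3[f$voxel_index] == 0))
})

test_that("intensity varying only along z aligns e3 with z and zeroes lambda1,2", {
  d <- c(16, 16, 16)
  arr <- array(rep((1:16)^1.5, each = 16 * 16), d)  # varies along z only
  v <- image_volume(arr, c(1, 1, 1))
  f <- gradient_structure_tensor(v, array(TRUE, d))
  ok <- which(!f$isotropic[f$voxel_index])
  idx <- f$voxel_index[ok]
  expect_lt(max(f$lambda1[idx], f$lambda2[idx]), 1e-12)
  expect_gt(min(abs(f$e3[ok, 3])), 1 - 1e-8)
  expect_equal(max(abs(f$DA[idx] - 1)), 0, tolerance = 1e-12)
})

test_that("eigenvectors rotate with a 90-degree rotation of the volume", {
  set.seed(5)
  d <- c(14, 14, 14)
  arr <- array(rnorm(prod(d)), d)
  arr <- hapcage:::gauss_smooth3(arr, c(1, 1, 2))  # anisotropic texture
  v <- image_volume(arr, c(1, 1, 1))
  lab <- array(TRUE, d)
  f1 <- gradient_structure_tensor(v, lab)
  # rotate volume 90 degrees about z: (x, y) -> (y, -x)
  arr_r <- aperm(arr, c(2, 1, 3))[, d[1]:1, ]
  f2 <- gradient_structure_tensor(image_volume(arr_r, c(1, 1, 1)), lab)
  # eigenvalues are rotation invariant (compare sorted interior values)
  i1 <- which(!f1$isotropic[f1$voxel_index])
  i2 <- which(!f2$isotropic[f2$voxel_index])
  expect_equal(sort(f1$DA[f1$voxel_index][i1]),
               sort(f2$DA[f2$voxel_index][i2]), tolerance = 1e-10)
  # the interior voxel with the widest eigen-gap (most stable vector):
  # e3 of the rotated volume equals the rotated e3
  gap <- (f1$lambda3 - f1$lambda2)[f1$voxel_index]
  gap[f1$isotropic[f1$voxel_index]] <- -Inf
  interior <- function(lin) {
    k <- (lin - 1) %/% (d[1] * d[2]) + 1
    j <- ((lin - 1) %% (d[1] * d[2])) %/% d[1] + 1
    i <- (lin - 1) %% d[1] + 1
    all(c(i, j, k) >= 5 & c(i, j, k) <= 10)
  }
  cand <- order(gap, decreasing = TRUE)
  r1 <- cand[which(vapply(f1$voxel_index[cand[1:200]], interior,
                          logical(1)))[1]]
  lin1 <- f1$voxel_index[r1]
  k1 <- (lin1 - 1) %/% (d[1] * d[2]) + 1
  j1 <- ((lin1 - 1) %% (d[1] * d[2])) %/% d[1] + 1
  i1 <- (lin1 - 1) %% d[1] + 1
  pr <- c(j1, d[1] + 1 - i1, k1)
  r2 <- match((pr[3] - 1) * d[1] * d[2] + (pr[2] - 1) * d[1] + pr[1],
              f2$voxel_index)
  # index map (i, j) -> (j, N+1-i) has linear part x' = y, y' = -x
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  e3r <- as.numeric(Rz %*% f1$e3[r1, ])
  cosang <- abs(sum(e3r * f2$e3[r2, ]))
  expect_gt(cosang, 1 - 1e-4)
})

test_that("boundary flag follows the 25% window-outside rule", {
  d <- c(20, 20, 20)
  lab <- array(FALSE, d)
  lab[, , 1:10] <- TRUE  # half-space
  fl <- boundary_flag(lab, window = 7, max_outside_fraction = 0.25)
  # counting oracle: voxel at slice k has (10 - k) full slices below the
  # boundary; outside fraction = max(0, k - 7) / 7 for k near the face
  expect_false(fl[10, 10, 5])              # deep interior
  expect_true(fl[10, 10, 10])              # at the face: ~3/7 outside
  oracle_outside <- function(k) {
    zs <- (k - 3):(k + 3)
    sum(zs > 10 | zs < 1) / 7
  }
  for (k in 4:10) {
    expect_identical(fl[10, 10, k], oracle_outside(k) > 0.25)
  }
  expect_false(any(boundary_flag(lab, 7, max_outside_fraction = 1)[lab]))
})

test_that("DA and aspect ratio formulas match direct substitution", {
  expect_equal(morphologic_anisotropy(1, 1), 0)
  expect_equal(morphologic_anisotropy(0, 2), 1)
  expect_equal(morphologic_anisotropy(1, 4), 0.75)
  expect_true(is.na(morphologic_anisotropy(0, 0)))
  ar <- aspect_ratio(1, 1)
  expect_equal(ar$R, 1)
  expect_equal(ar$theta, pi / 4)
  expect_equal(aspect_ratio(1, 3)$R, 3)
  # DA = 0.38 => lambda1/lambda3 = 0.62 => R = 1/0.62
  expect_equal(aspect_ratio(0.62, 1)$R, 1 / 0.62, tolerance = 1e-12)
  expect_equal(aspect_ratio(0, 1)$R, 10)  # capped
  expect_equal(aspect_ratio(0, 1, r_max = 5)$R, 5)
})

test_that("GST matches a dense brute-force implementation on a random volume", {
  set.seed(9)
  d <- c(9, 9, 9)
  arr <- array(rnorm(prod(d)), d)
  v <- image_volume(arr, c(0.5, 0.5, 0.5))
  lab <- array(TRUE, d)
  lab[1:2, , ] <- FALSE  # irregular label to exercise masking
  f <- gradient_structure_tensor(v, lab, window = 5,
                                 max_outside_fraction = 0.9)
  ref <- brute_force_gst(v, lab, window = 5)
  for (entry in ref[seq(1, length(ref), by = 17)]) {
    lin <- (entry$k - 1) * d[1] * d[2] + (entry$j - 1) * d[1] + entry$i
    row <- match(lin, f$voxel_index)
    ev <- eigen(entry$M, symmetric = TRUE)$values
    expect_equal(c(f$lambda1[lin], f$lambda2[lin], f$lambda3[lin]),
                 sort(ev), tolerance = 1e-10)
  }
})

test_that("DA is invariant under uniform intensity scaling", {
  ph <- oriented_phantom()
  lab <- ph$truth$labels == 2L
  f1 <- oriented_fabric()
  v2 <- image_volume(ph$volume$values * 7.3, ph$volume$spacing,
                     ph$volume$origin)
  f2 <- gradient_structure_tensor(v2, lab)
  expect_equal(f1$DA[f1$voxel_index], f2$DA[f2$voxel_index],
               tolerance = 1e-10)
})

test_that("fabric summary reports pooled anisotropy and angular error", {
  f <- oriented_fabric()
  s <- fabric_summary(f, reference_direction = c(0, 0, 1))
  expect_true(s$pooled_DA > 0.3 && s$pooled_DA < 0.75)
  expect_lt(s$median_angle_deg, 15)
  expect_gte(s$median_R, 1)
})
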