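# Linear-static tetrahedral solver and the damage post-processing.

test_that("constant-strain patch test is exact", {
  mesh <- block_mesh(3, 3, 3, h = 1)
  mats <- iso_materials(mesh, 1000, 0.3)
  eps <- c(1e-3, -4e-4, 2e-4, 3e-4, -2e-4, 5e-4)  # arbitrary uniform strain
  epsm <- matrix(c(eps[1], eps[6] / 2, eps[5] / 2,
                   eps[6] / 2, eps[2], eps[4] / 2,
                   eps[5] / 2, eps[4] / 2, eps[3]), 3, 3)
  # prescribe the affine field on all boundary nodes
  bnodes <- which(apply(mesh$nodes, 1, function(p)
    any(abs(p - min(mesh$nodes)) < 1e-9 | abs(p - max(mesh$nodes)) < 1e-9)))
  uvals <- mesh$nodes[bnodes, ] %*% t(epsm)
  dofs <- as.vector(t(cbind(3 * (bnodes - 1) + 1, 3 * (bnodes - 1) + 2,
                            3 * (bnodes - 1) + 3)))
  res <- solve_linear_static(mesh, mats, integer(0),
                             prescribed = list(dofs = dofs,
                                               values = as.vector(t(uvals))))
  expect_lt(max(abs(res$strain - eps)), 1e-10)
  sigma <- iso_stiffness(1000, 0.3) %*% eps
  expect_lt(max(abs(res$stress - as.numeric(sigma))), 1e-8)
})

test_that("isotropic block under uniaxial load: sigma = F/A, lateral = -nu*axial", {
  mesh <- block_mesh(4, 4, 8, h = 1)
  mats <- iso_materials(mesh, 1000, 0.3)
  zr <- range(mesh$nodes[, 3])
  xr <- range(mesh$nodes[, 1])
  yr <- range(mesh$nodes[, 2])
  # roller supports: bottom uz = 0, plus minimal lateral restraints
  bot <- select_nodes(mesh, function(x, y, z) z < zr[1] + 0.5)
  corner <- select_nodes(mesh, function(x, y, z)
    z < zr[1] + 0.5 & x < xr[1] + 0.5 & y < yr[1] + 0.5)[1]
  corner2 <- select_nodes(mesh, function(x, y, z)
    z < zr[1] + 0.5 & x > xr[2] - 0.5 & y < yr[1] + 0.5)[1]
  dofs <- c(3 * (bot - 1) + 3, 3 * (corner - 1) + 1:2, 3 * (corner2 - 1) + 2)
  # uniform traction on the top face via consistent nodal forces
  top <- select_nodes(mesh, function(x, y, z) z > zr[2] - 0.5)
  # lumped equivalent loads: total F spread by tributary area
  f <- numeric(3 * nrow(mesh$nodes))
  xpos <- mesh$nodes[top, 1]; ypos <- mesh$nodes[top, 2]
  wx <- ifelse(xpos %in% range(xpos), 0.5, 1)
  wy <- ifelse(ypos %in% range(ypos), 0.5, 1)
  w <- wx * wy
  F_total <- -160
  f[3 * (top - 1) + 3] <- F_total * w / sum(w)
  res <- solve_linear_static(mesh, mats, integer(0), nodal_forces = f,
                             prescribed = list(dofs = dofs,
                                               values = numeric(length(dofs))))
  expect_equal(mean(res$stress[3, ]), -10, tolerance = 1e-6)
  expect_equal(mean(res$strain[1, ]), 0.3 * 10 / 1000, tolerance = 1e-6)
  expect_lt(res$equilibrium_residual, 1e-8)
})

test_that("slender cantilever converges to the Euler-Bernoulli deflection", {
  n <- 6
  h <- 2 / n
  mesh <- make_tet_mesh(image_volume(array(1L, c(n, n, 10 * n)), rep(h, 3)), h)
  mats <- iso_materials(mesh, 1000, 0)
  zr <- range(mesh$nodes[, 3])
  fixed <- select_nodes(mesh, function(x, y, z) z < zr[1] + h / 2)
  top <- select_nodes(mesh, function(x, y, z) z > zr[2] - h / 2)
  res <- solve_linear_static(mesh, mats, fixed,
                             coupling = list(ref_point = c(1, 1, zr[2] + 1e-6),
                                             nodes = top),
                             load = list(force = c(1, 0, 0),
                                         moment = c(0, 0, 0)))
  eb <- 20^3 / (3 * 1000 * 2^4 / 12)
  expect_lt(abs(res$rp_disp[1] - eb) / eb, 0.10)
  expect_lt(res$equilibrium_residual, 1e-6)
})

test_that("doubling the load doubles displacement, stiffness unchanged", {
  mesh <- block_mesh(3, 3, 6, h = 1)
  mats <- iso_materials(mesh)
  zr <- range(mesh$nodes[, 3])
  fixed <- select_nodes(mesh, function(x, y, z) z < zr[1] + 0.5)
  top <- select_nodes(mesh, function(x, y, z) z > zr[2] - 0.5)
  cpl <- list(ref_point = c(1.5, 1.5, zr[2] + 1), nodes = top)
  r1 <- solve_linear_static(mesh, mats, fixed, coupling = cpl,
                            load = list(force = c(0, 0, -100),
                                        moment = c(0, 0, 0)))
  r2 <- solve_linear_static(mesh, mats, fixed, coupling = cpl,
                            load = list(force = c(0, 0, -200),
                                        moment = c(0, 0, 0)))
  expect_equal(2 * r1$rp_disp[3], r2$rp_disp[3], tolerance = 1e-9)
  m1 <- macroscopic_response(r1, list(force = c(0, 0, -100)))
  m2 <- macroscopic_response(r2, list(force = c(0, 0, -200)))
  expect_equal(m1$stiffness_kN_mm, m2$stiffness_kN_mm, tolerance = 1e-9)
})

test_that("failed-volume and trabecular-damage counters match constructed fields", {
  # constructed result: 10 elements of equal volume, 1 above tension
  # threshold, 2 below the compressive strain limit
  ps <- matrix(0, 3, 10)
  ps[3, 4] <- 150      # max principal stress above 100
  ps[1, 7] <- -400     # min principal stress beyond -350
  pe <- matrix(0, 3, 10)
  pe[1, c(2, 9)] <- -0.01
  fake <- structure(list(principal_stress = ps, principal_strain = pe,
                         volume = rep(2, 10)), class = "fe_result")
  expect_equal(failed_volume(fake, 1:10, 100, 350, "tension"), 10)
  expect_equal(failed_volume(fake, 1:10, 100, 350, "compression"), 10)
  expect_equal(failed_volume(fake, 1:10, 100, 350, "either"), 20)
  expect_equal(damaged_trabecular_volume(fake, 1:10, 0.0084), 20)
  # all-zero stress -> 0%
  fake0 <- structure(list(principal_stress = matrix(0, 3, 4),
                          principal_strain = matrix(0, 3, 4),
                          volume = rep(1, 4)), class = "fe_result")
  expect_equal(failed_volume(fake0, 1:4, 100, 350), 0)
  expect_equal(damaged_trabecular_volume(fake0, 1:4), 0)
  expect_error(failed_volume(fake, integer(0), 1, 1), "empty")
})

test_that("damage percentages are monotone as thresholds decrease", {
  set.seed(8)
  ps <- matrix(rnorm(300, sd = 80), 3, 100)
  ps <- apply(ps, 2, sort)
  fake <- structure(list(principal_stress = ps, volume = runif(100, 1, 2)),
                    class = "fe_result")
  lims <- c(200, 100, 50, 20)
  fv <- vapply(lims, function(L) failed_volume(fake, 1:100, L, L), numeric(1))
  expect_true(all(diff(fv) >= 0))
  # union at least as large as each single mode
  expect_gte(failed_volume(fake, 1:100, 50, 50, "either"),
             max(failed_volume(fake, 1:100, 50, 50, "tension"),
                 failed_volume(fake, 1:100, 50, 50, "compression")))
})

test_that("macroscopic response recovers a known spring stiffness", {
  fake <- structure(list(rp_disp = c(0, 0, -0.05), rp_rot = c(1e-4, 0, 0)),
                    class = "fe_result")
  m <- macroscopic_response(fake, list(force = c(0, 0, -500)))
  expect_equal(m$stiffness_kN_mm, 10)
  expect_equal(m$rotation_deg, 1e-4 * 180 / pi)
  fake0 <- structure(list(rp_disp = c(0, 0, 0), rp_rot = c(0, 0, 0)),
                     class = "fe_result")
  expect_error(macroscopic_response(fake0, list(force = c(0, 0, -1))), "zero")
})

test_that("global equilibrium holds to 1e-6 relative on a mixed model", {
  mesh <- block_mesh(3, 3, 6, h = 1)
  mats <- iso_materials(mesh)
  mats[, seq(1, ncol(mats), by = 3)] <-
    pack_voigt(ti_stiffness(5000, 2000, 0.3, 0.3, 900))
  zr <- range(mesh$nodes[, 3])
  fixed <- select_nodes(mesh, function(x, y, z) z < zr[1] + 0.5)
  top <- select_nodes(mesh, function(x, y, z) z > zr[2] - 0.5)
  res <- solve_linear_static(mesh, mats, fixed,
                             coupling = list(ref_point = c(1.5, 1.5, zr[2] + 2),
                                             nodes = top),
                             load = list(force = c(10, 5, -50),
                                         moment = c(500, 0, 200)))
  expect_lt(res$equilibrium_residual, 1e-6)
  # reactions balance applied load
  react <- colSums(res$reactions[fixed, , drop = FALSE])
  expect_equal(react, -c(10, 5, -50), tolerance = 1e-6, ignore_attr = TRUE)
})
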