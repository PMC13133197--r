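# Micromechanics: Mori-Tanaka inclusion models, Kelvin-cell dual routes,
# stiffness rotation, nearest-voxel assignment.

test_that("cortical model returns the matrix stiffness at zero porosity", {
  C <- cortical_stiffness(0)
  expect_equal(C, iso_stiffness(20000, 0.3), tolerance = 1e-12)
})

test_that("dilute limit matches the closed-form dilute Eshelby estimate", {
  p <- cortical_model_params()
  f <- 1e-4
  C0 <- iso_stiffness(p$matrix_E, p$matrix_nu)
  C1 <- hapcage:::water_stiffness(p$water_K)
  S <- hapcage:::eshelby_voigt(p$matrix_nu, "cylinder")
  Tdil <- solve(diag(6) + S %*% solve(C0, C1 - C0))
  C_dilute <- C0 + f * (C1 - C0) %*% Tdil
  C_mt <- cortical_stiffness(f)
  expect_lt(max(abs(C_mt - C_dilute)) / max(abs(C0)), 1e-7)
})

test_that("cortical axial modulus band and anisotropy ordering", {
  for (phi in c(0.05, 0.1, 0.15)) {
    S <- solve(cortical_stiffness(phi))
    E_ax <- 1 / S[3, 3] / 1000
    E_tr <- 1 / S[1, 1] / 1000
    expect_gt(E_ax, 15)
    expect_lt(E_ax, 19.5)
    expect_lt(E_tr, E_ax)
  }
})

test_that("spherical fallback is isotropic, monotone, and below the Voigt bound", {
  C0 <- isotropic_fallback_stiffness(0)
  expect_equal(C0, iso_stiffness(20000, 0.3), tolerance = 1e-9)
  Es <- vapply(seq(0, 0.9, by = 0.1), function(p) {
    S <- solve(isotropic_fallback_stiffness(p))
    1 / S[1, 1]
  }, numeric(1))
  expect_true(all(diff(Es) < 0))
  # shear modulus vanishes as porosity -> 1
  Cnear <- isotropic_fallback_stiffness(0.999)
  expect_lt(Cnear[4, 4], 10)
  # Voigt mixture bound
  for (p in c(0.2, 0.5, 0.8)) {
    Cv <- (1 - p) * iso_stiffness(20000, 0.3) +
      p * hapcage:::water_stiffness()
    Cm <- isotropic_fallback_stiffness(p)
    ev <- eigen(Cv - Cm, symmetric = TRUE)$values
    expect_gt(min(ev), -1e-6 * max(abs(Cv)))
  }
})

test_that("Kelvin cell geometry follows the elongated-cell relations", {
  p <- kelvin_cell_params(1.7, 0.85, 13000)
  expect_equal(p$H / p$D, tan(p$theta))
  expect_equal(p$H / p$D, 1.7, tolerance = 1e-12)
  expect_equal(p$b, sqrt(2) * p$L * cos(p$theta))
  expect_equal(p$A, pi * p$r^2)
  expect_equal(p$I, pi * p$r^4 / 4)
  expect_equal(p$J, pi * p$r^4 / 2)
  # density closure: recompute porosity from the strut volume relation
  rho <- pi * p$r^2 * (2 + sqrt(2) * cos(p$theta)) /
    (8 * p$L^2 * cos(p$theta)^2 * sin(p$theta))
  expect_equal(rho, 0.15, tolerance = 1e-12)
  expect_error(kelvin_cell_params(1, 0.05, 1000), "r/L")
})

test_that("Kelvin constants: equiaxed symmetry, E0 linearity, vanishing density", {
  k1 <- kelvin_cell_constants(1, 0.8, 1000)
  expect_equal(k1$E_axial, k1$E_trans, tolerance = 1e-9)
  k2 <- kelvin_cell_constants(1.6, 0.85, 1000)
  k2b <- kelvin_cell_constants(1.6, 0.85, 2000)
  expect_equal(2 * k2$E_axial, k2b$E_axial, tolerance = 1e-9)
  expect_equal(2 * k2$G_axial, k2b$G_axial, tolerance = 1e-9)
  expect_equal(k2$nu_axial, k2b$nu_axial, tolerance = 1e-9)
  knear <- kelvin_cell_constants(1.5, 0.999, 1000)
  expect_lt(knear$E_axial, 1e-2)
  # elongation stiffens the rise direction
  expect_gt(k2$E_axial, k2$E_trans)
})

test_that("trabecular-scale constants are in the hundreds of MPa", {
  k <- kelvin_cell_constants(1.7, 0.85, 13000)
  expect_gt(k$E_axial, 100)
  expect_lt(k$E_axial, 1000)
  expect_gt(k$E_axial / k$E_trans, 2)
  expect_lt(k$E_axial / k$E_trans, 8)
})

test_that("beam-frame oracle: linearity in E0 and bounded rigid limit", {
  p <- kelvin_cell_params(1.3, 0.85, 1000)
  o1 <- beam_frame_unit_cell_oracle(p)
  p2 <- kelvin_cell_params(1.3, 0.85, 2000)
  o2 <- beam_frame_unit_cell_oracle(p2)
  expect_equal(2 * o1$E_axial, o2$E_axial, tolerance = 1e-9)
  expect_equal(2 * o1$G_axial, o2$G_axial, tolerance = 1e-9)
  # fattest admissible struts: stiffness stays a finite fraction of E0
  pf <- kelvin_cell_params(1, 1 - 0.7493, 1000)  # r/L just under 0.5
  of <- beam_frame_unit_cell_oracle(pf)
  expect_lt(of$E_axial, 1000)
  expect_gt(of$E_axial, 1)
})

test_that("analytic constants track the beam-frame oracle within 10%", {
  for (R in c(1, 1.8, 3)) for (phi in c(0.72, 0.85, 0.92)) {
    kc <- kelvin_cell_constants(R, phi, 1000)
    ko <- beam_frame_unit_cell_oracle(kelvin_cell_params(R, phi, 1000))
    expect_lt(abs(kc$E_axial - ko$E_axial) / ko$E_axial, 0.10)
    expect_lt(abs(kc$E_trans - ko$E_trans) / ko$E_trans, 0.10)
    expect_lt(abs(kc$G_axial - ko$G_axial) / ko$G_axial, 0.10)
    expect_lt(abs(kc$nu_trans - ko$nu_trans), 0.05)
  }
})

test_that("oracle modulus scales like the square of relative density", {
  rhos <- c(0.05, 0.1, 0.2, 0.3)
  Es <- vapply(rhos, function(r)
    beam_frame_unit_cell_oracle(kelvin_cell_params(1, 1 - r, 1000))$E_axial,
    numeric(1))
  slope <- coef(lm(log(Es) ~ log(rhos)))[2]
  expect_gt(slope, 1.5)
  expect_lt(slope, 2.5)
})

test_that("stiffness rotation preserves symmetry, isotropy and round-trips", {
  C <- ti_stiffness(400, 160, 0.9, 0.3, 80)
  Q <- cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  Cw <- rotate_stiffness(C, Q)
  expect_equal(Cw, t(Cw), tolerance = 1e-9)
  # axial modulus moved from local 3 to world x
  expect_equal(Cw[1, 1], C[3, 3], tolerance = 1e-9)
  expect_equal(Cw[3, 3], C[1, 1], tolerance = 1e-9)
  # isotropic tensor invariant under arbitrary rotation
  ang <- 0.83
  Qz <- cbind(c(cos(ang), sin(ang), 0), c(-sin(ang), cos(ang), 0), c(0, 0, 1))
  Ci <- iso_stiffness(1234, 0.27)
  expect_equal(rotate_stiffness(Ci, Qz), Ci, tolerance = 1e-9)
  # inverse rotation is the identity to 1e-10
  back <- rotate_stiffness(rotate_stiffness(C, Qz), t(Qz))
  expect_equal(back, C, tolerance = 1e-10)
  expect_error(rotate_stiffness(C, matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 2), 3)),
               "orthonormal")
})

test_that("produced stiffnesses are symmetric positive definite", {
  set.seed(4)
  for (i in 1:10) {
    phi <- runif(1, 0.6, 0.92)
    R <- runif(1, 1, 3)
    C <- kelvin_cell_constants(R, phi, 13000)$C
    expect_lt(max(abs(C - t(C))), 1e-9 * max(abs(C)))
    expect_gt(min(eigen(C, symmetric = TRUE)$values), 0)
    Cc <- cortical_stiffness(runif(1, 0, 0.5))
    expect_gt(min(eigen(Cc, symmetric = TRUE)$values), 0)
  }
})

test_that("nearest-voxel assignment matches brute force and breaks ties low", {
  # two-voxel field along x
  idx <- array(0L, c(2, 1, 1))
  idx[1] <- 1L; idx[2] <- 2L
  C21 <- cbind(pack_voigt(iso_stiffness(100, 0.3)),
               pack_voigt(iso_stiffness(200, 0.3)))
  field <- structure(list(index = idx, C21 = C21, tissue = c(1L, 1L),
                          spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          dim = c(2L, 1L, 1L)), class = "elasticity_field")
  set.seed(6)
  nodes <- cbind(runif(30, -0.4, 1.4), runif(30, -0.4, 0.4),
                 runif(30, -0.4, 0.4))
  elems <- matrix(sample(30, 24, replace = TRUE), ncol = 4)
  keep <- apply(elems, 1, function(r) length(unique(r)) == 4)
  mesh <- tet_mesh(nodes, elems[keep, , drop = FALSE])
  mats <- nearest_voxel_assign(mesh, field)
  cen <- element_centroids(mesh)
  centres <- rbind(c(0, 0, 0), c(1, 0, 0))
  for (e in seq_len(nrow(mesh$elems))) {
    d2 <- colSums((t(centres) - cen[e, ])^2)
    expect_equal(mats[1, e], C21[1, which.min(d2)])
  }
  # exact tie at x = 0.5 resolves to the lower linear index
  mesh_t <- tet_mesh(rbind(c(0.5, -0.1, -0.1), c(0.9, 0.166, -0.066),
                           c(0.1, 0.166, -0.066), c(0.5, -0.066, 0.434)),
                     matrix(1:4, 1))
  cen_t <- element_centroids(mesh_t)
  expect_equal(cen_t[1], 0.5)  # centroid exactly halfway
  mt <- nearest_voxel_assign(mesh_t, field)
  expect_equal(mt[1, 1], C21[1, 1])
  # uniform field: all elements identical
  idx2 <- array(1L, c(2, 1, 1))
  fu <- structure(list(index = idx2, C21 = C21[, 1, drop = FALSE],
                       tissue = 1L, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), dim = c(2L, 1L, 1L)),
                  class = "elasticity_field")
  mu <- nearest_voxel_assign(mesh, fu)
  expect_true(all(mu == mu[, 1]))
})

test_that("uncovered elements take the default and are reported", {
  idx <- array(0L, c(2, 2, 2)); idx[1] <- 1L
  field <- structure(list(index = idx,
                          C21 = matrix(pack_voigt(iso_stiffness(50, 0.3))),
                          tissue = 1L, spacing = c(1, 1, 1),
                          origin = c(0, 0, 0), dim = c(2L, 2L, 2L)),
                     class = "elasticity_field")
  mesh <- block_mesh(2, 2, 2, h = 1)
  expect_error(nearest_voxel_assign(mesh, field), "default_stiffness")
  mats <- nearest_voxel_assign(mesh, field, iso_stiffness(1, 0.3))
  expect_gt(attr(mats, "n_default"), 0)
})
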