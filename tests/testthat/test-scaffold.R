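# Cage geometry, lattice generation, porosity measurement, strength law.

test_that("the strength scaling law evaluates exactly", {
  expect_equal(round(macroscopic_strength(100, 0.75), 2), 1.89)
  expect_equal(round(macroscopic_strength(350, 0.75), 2), 6.62)
  expect_equal(macroscopic_strength(100, 0.75), 1.21 * 0.25^3 * 100)
  expect_equal(macroscopic_strength(200, 0), 1.21 * 200)
  expect_error(macroscopic_strength(100, 1), "phi")
})

test_that("uniform lattices hit the 75% porosity target within 1%", {
  fp <- cage_footprint()
  for (fam in c("fcc", "kelvin")) {
    m <- generate_lattice(fp, lattice_spec(fam, cell_size = 3),
                          resolution_mm = 0.3)
    expect_lt(abs(m$porosity - 0.75), 0.01)
    expect_lt(abs(measure_porosity(m) - 0.75), 0.01)
  }
  mv <- generate_lattice(fp, lattice_spec("voronoi", cell_size = 2.5,
                                          seed = 11), resolution_mm = 0.3)
  expect_lt(abs(mv$porosity - 0.75), 0.01)
})

test_that("large strut radius drives porosity to zero", {
  fp <- cage_footprint()
  m <- generate_lattice(fp, lattice_spec("fcc", cell_size = 3,
                                         strut_radius = 1.6),
                        resolution_mm = 0.4)
  expect_lt(m$porosity, 0.01)
})

test_that("the same Voronoi seed reproduces the identical lattice", {
  fp <- cage_footprint()
  a <- generate_lattice(fp, lattice_spec("voronoi", cell_size = 2.5,
                                         seed = 4), resolution_mm = 0.4)
  b <- generate_lattice(fp, lattice_spec("voronoi", cell_size = 2.5,
                                         seed = 4), resolution_mm = 0.4)
  expect_identical(a$occ, b$occ)
})

test_that("graded Voronoi hits its radial endpoints and is monotone", {
  fp <- cage_footprint()
  m <- generate_lattice(fp, lattice_spec("voronoi", cell_size = 2.5,
                                         gradient = "radial", seed = 11),
                        resolution_mm = 0.3)
  inner <- m$inside & m$rho <= 1 / 3
  outer <- m$inside & m$rho >= 0.8
  expect_lt(abs((1 - mean(m$occ[inner])) - 0.90), 0.03)
  expect_lt(abs((1 - mean(m$occ[outer])) - 0.60), 0.03)
  prof <- measure_porosity(m, "radial_bins", n_bins = 4)
  expect_true(all(diff(prof$porosity) < 0.03))  # decreasing axis -> rim
})

test_that("Ti ring matches the analytic ellipse porosity and wall ratio", {
  fp <- cage_footprint()
  ring <- generate_ti_ring(fp)
  a <- fp$half_axes[1]; b <- fp$half_axes[2]; w <- 3.8
  analytic <- 1 - (a * b - (a - w) * (b - w)) / (a * b)
  expect_lt(abs(ring$porosity - analytic), 0.01)
  expect_equal(3.8 / 32, 0.11875)  # wall to maximum diameter, about 12%
  # boolean conservation: ring + core volumes = footprint volume
  core <- sum(ring$inside) - sum(ring$occ)
  expect_equal(core + sum(ring$occ), sum(ring$inside))
  expect_error(generate_ti_ring(fp, wall_mm = 14), "semi-minor")
})

test_that("Monte-Carlo porosity agrees with voxel counting", {
  fp <- cage_footprint()
  ring <- generate_ti_ring(fp)
  set.seed(1)
  p <- measure_porosity(ring, method = "mc", n_mc = 2e5)
  expect_lt(abs(p - ring$porosity), 5 * attr(p, "se") + 0.005)
})

test_that("scaffold surface triangulation is watertight", {
  fp <- cage_footprint(c(10, 12), 5)
  m <- generate_lattice(fp, lattice_spec("fcc", cell_size = 3),
                        resolution_mm = 0.8)
  s <- scaffold_surface(m)
  # closed surface: directed edges balance their reversals everywhere
  # (voxel surfaces are non-manifold along checkerboard edges, so counts
  # can exceed one, but a closed surface keeps them equal)
  edges <- rbind(s$faces[, c(1, 2)], s$faces[, c(2, 3)], s$faces[, c(3, 1)])
  key <- paste(edges[, 1], edges[, 2])
  rkey <- paste(edges[, 2], edges[, 1])
  tk <- table(key)
  tr <- table(rkey)
  expect_setequal(names(tk), names(tr))
  expect_equal(as.integer(tk[names(tk)]), as.integer(tr[names(tk)]))
})
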