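# Voxel-to-tetrahedra meshing and text-format IO.

test_that("a labelled cube meshes into 6 tets per cell conserving volume", {
  m <- make_tet_mesh(image_volume(array(1L, c(4, 4, 4)), rep(0.25, 3)), 0.25)
  q <- mesh_quality(m)
  expect_equal(nrow(m$elems), 4^3 * 6)
  expect_equal(sum(q$volume), 1, tolerance = 1e-12)
  expect_true(all(q$volume > 0))
})

test_that("sphere mesh volume approaches the analytic volume", {
  d <- c(40, 40, 40)
  h <- 0.5
  xs <- ((1:40) - 20.5) * h
  X <- array(xs, d)
  Y <- array(rep(xs, each = 40), d)
  Z <- array(rep(xs, each = 1600), d)
  sph <- array(as.integer(X^2 + Y^2 + Z^2 <= 64), d)
  m <- make_tet_mesh(image_volume(sph, rep(h, 3), rep(xs[1], 3)), h)
  vol <- sum(mesh_quality(m)$volume)
  expect_lt(abs(vol - 4 / 3 * pi * 512) / (4 / 3 * pi * 512), 0.05)
})

test_that("empty labels fail loudly", {
  expect_error(make_tet_mesh(image_volume(array(0L, c(4, 4, 4))), 1), "empty")
})

test_that("priority sampling keeps a thin shell that centre sampling loses", {
  d <- c(24, 24, 24)
  lab <- array(0L, d)
  lab[3:22, 3:22, 3:22] <- 2L
  lab[4, , ] <- ifelse(lab[4, , ] > 0, 1L, 0L)  # one-voxel shell face
  # (cell centres fall at voxel indices 3, 7, ... so centre sampling never
  # sees index 4)
  v <- image_volume(lab, rep(0.5, 3))
  m_centre <- make_tet_mesh(v, 2)
  m_prior <- make_tet_mesh(v, 2, priority = rbind(c(1, 0.2)))
  expect_equal(sum(m_centre$elem_label == 1L), 0)
  expect_gt(sum(m_prior$elem_label == 1L), 0)
})

test_that("INP export round-trips nodes, elements and region sets", {
  m <- make_tet_mesh(image_volume(array(rep(1:2, each = 32), c(4, 4, 4))), 1)
  path <- tempfile(fileext = ".inp")
  write_inp(m, path, materials = list("1" = iso_stiffness(1000, 0.3)))
  m2 <- read_inp(path)
  expect_equal(m2$nodes, m$nodes, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m2$elems, m$elems)
  expect_equal(sort(unique(m2$elem_label)), sort(unique(m$elem_label)))
})

test_that("VTK and STL writers emit parseable text", {
  m <- block_mesh(2, 2, 2)
  vp <- tempfile(fileext = ".vtk")
  write_vtk(m, vp, cell_data = list(x = seq_len(nrow(m$elems)) * 1.0))
  lines <- readLines(vp)
  expect_true(any(grepl("UNSTRUCTURED_GRID", lines)))
  expect_equal(sum(grepl("^4 ", lines)), nrow(m$elems))
  sp <- tempfile(fileext = ".stl")
  tri <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
              faces = rbind(c(1, 2, 3)))
  write_stl(tri$vertices, tri$faces, sp)
  expect_true(any(grepl("facet normal", readLines(sp))))
})
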