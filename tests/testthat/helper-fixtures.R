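# Shared lazily-built fixtures (phantoms and models are expensive; build
# once per test run).

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  v <- get0(name, envir = .fix)
  if (is.null(v)) {
    v <- builder()
    assign(name, v, envir = .fix)
  }
  v
}

small_phantom_spec <- function(anisotropy = 0.5, seed = 7,
                               spacing = rep(0.326, 3)) {
  phantom_spec(body_half_axes = c(11, 9, 8), spacing = spacing,
               texture_anisotropy = anisotropy, seed = seed)
}

oriented_phantom <- function() {
  fixture("oriented_phantom", function() {
    make_vertebra_phantom(small_phantom_spec(anisotropy = 0.5, seed = 7))
  })
}

isotropic_phantom <- function() {
  fixture("isotropic_phantom", function() {
    make_vertebra_phantom(small_phantom_spec(anisotropy = 0, seed = 3))
  })
}

oriented_fabric <- function() {
  fixture("oriented_fabric", function() {
    ph <- oriented_phantom()
    gradient_structure_tensor(ph$volume, ph$truth$labels == 2L)
  })
}

# small uniform block mesh with isotropic material
block_mesh <- function(nx = 4, ny = 4, nz = 8, h = 1) {
  make_tet_mesh(image_volume(array(1L, c(nx, ny, nz)), rep(h, 3)), h)
}

iso_materials <- function(mesh, E = 1000, nu = 0.3) {
  matrix(pack_voigt(iso_stiffness(E, nu)), 21, nrow(mesh$elems))
}

# dense brute-force GST for oracle comparisons (small volumes only)
brute_force_gst <- function(vol, label, window = 7) {
  d <- dim(vol$values)
  sp <- vol$spacing
  g <- list(array(0, d), array(0, d), array(0, d))
  for (a in 1:3) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      idx <- c(i, j, k)
      ip <- idx; im <- idx
      ip[a] <- min(idx[a] + 1, d[a]); im[a] <- max(idx[a] - 1, 1)
      g[[a]][i, j, k] <- (vol$values[ip[1], ip[2], ip[3]] -
                            vol$values[im[1], im[2], im[3]]) /
        ((ip[a] - im[a]) * sp[a])
    }
  }
  r <- (window - 1) / 2
  out <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!label[i, j, k]) next
    M <- matrix(0, 3, 3)
    cnt <- 0
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
        next
      if (!label[ii, jj, kk]) next
      gv <- c(g[[1]][ii, jj, kk], g[[2]][ii, jj, kk], g[[3]][ii, jj, kk])
      M <- M + outer(gv, gv)
      cnt <- cnt + 1
    }
    M <- M / cnt
    if (sum(diag(M)) > 0) M <- M / sum(diag(M))
    out[[length(out) + 1]] <- list(i = i, j = j, k = k, M = M)
  }
  out
}
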