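# Voxel-by-voxel micromechanics: cylindrical-inclusion model for cortical
# bone, elongated Kelvin-cell open foam for trabecular bone, and mapping of
# per-voxel stiffness onto tetrahedral elements.

#' Cortical micromechanical model parameters
#'
#' Mineralized isotropic matrix with water-filled inclusions: infinite
#' cylinders along the local stiff axis (Haversian canals) for voxels with
#' resolved stiffness directions, spheres for voxels flagged isotropic.
#'
#' @param matrix_E matrix Young's modulus in MPa (default 20 GPa, the
#'   highest cortical stiffness reported for the mineralized matrix).
#' @param matrix_nu matrix Poisson ratio.
#' @param water_K inclusion (water) bulk modulus in MPa; zero shear.
#' @param inclusion_shape `"cylinder"` or `"sphere"`.
#' @return object of class `cortical_model_params`.
#' @export
cortical_model_params <- function(matrix_E = 20000, matrix_nu = 0.3,
                                  water_K = 2200,
                                  inclusion_shape = c("cylinder", "sphere")) {
  stopifnot(matrix_E > 0, matrix_nu > 0, matrix_nu < 0.5, water_K >= 0)
  structure(list(matrix_E = matrix_E, matrix_nu = matrix_nu,
                 water_K = water_K,
                 inclusion_shape = match.arg(inclusion_shape)),
            class = "cortical_model_params")
}

#' Cortical bone stiffness from porosity
#'
#' Mori-Tanaka estimate for water-filled infinite cylindrical inclusions in
#' an isotropic mineralized matrix; transversely isotropic, cylinder axis
#' along local axis 3 (the stiff material axis). At zero porosity the matrix
#' stiffness is returned exactly.
#'
#' @param porosity vascular porosity in `[0, 0.5]`; values above 0.5 are
#'   clamped (with a warning attribute).
#' @param params a [cortical_model_params].
#' @return 6x6 Voigt stiffness (MPa) in the local frame.
#' @export
cortical_stiffness <- function(porosity, params = cortical_model_params()) {
  stopifnot(inherits(params, "cortical_model_params"), length(porosity) == 1)
  clamped <- porosity > 0.5
  porosity <- min(max(porosity, 0), 0.5)
  C0 <- iso_stiffness(params$matrix_E, params$matrix_nu)
  C <- mori_tanaka(C0, water_stiffness(params$water_K), porosity,
                   eshelby_voigt(params$matrix_nu, "cylinder"))
  if (clamped) attr(C, "clamped") <- TRUE
  C
}

#' Isotropic fallback stiffness (spherical inclusions)
#'
#' Mori-Tanaka estimate for water-filled spherical inclusions in the
#' isotropic matrix; used for voxels flagged isotropic by the boundary rule.
#' Monotonically decreasing in porosity.
#'
#' @param porosity pore volume fraction in `[0, 1)`.
#' @param params a [cortical_model_params].
#' @return 6x6 isotropic Voigt stiffness (MPa).
#' @export
isotropic_fallback_stiffness <- function(porosity,
                                         params = cortical_model_params()) {
  stopifnot(porosity >= 0, porosity < 1)
  C0 <- iso_stiffness(params$matrix_E, params$matrix_nu)
  mori_tanaka(C0, water_stiffness(params$water_K), porosity,
              eshelby_voigt(params$matrix_nu, "sphere"))
}

# ---- elongated Kelvin cell ------------------------------------------------

# Periodic graph of the Kelvin (truncated octahedron) foam: 12 nodes and 24
# struts per period box, unscaled integer coordinates (period 4). Cached.
kelvin_cell_graph <- function() {
  cache <- get0(".kelvin_graph", envir = .hapcage_env)
  if (!is.null(cache)) return(cache)
  base <- rbind(c(0, 1, 2), c(0, 2, 1), c(1, 0, 2), c(1, 2, 0),
                c(2, 0, 1), c(2, 1, 0))
  sgn <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  verts <- unique(do.call(rbind, lapply(seq_len(6), function(i)
    t(t(sgn) * base[i, ]))))
  verts <- rbind(verts, sweep(verts, 2, c(2, 2, 2), "+"))
  nodes <- unique(verts %% 4)
  stopifnot(nrow(nodes) == 12)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * 4
  edges <- NULL
  for (i in 1:12) for (j in 1:12) for (k in seq_len(nrow(shifts))) {
    d <- nodes[j, ] + shifts[k, ] - nodes[i, ]
    if (abs(sum(d^2) - 2) < 1e-9) {
      key <- c(i, j, shifts[k, ])
      rkey <- c(j, i, -shifts[k, ])
      if (paste(key, collapse = ",") < paste(rkey, collapse = ",")) next
      edges <- rbind(edges, key)
    }
  }
  edges <- unique(edges)
  stopifnot(nrow(edges) == 24)
  out <- list(nodes = nodes, edges = edges)
  assign(".kelvin_graph", out, envir = .hapcage_env)
  out
}

.hapcage_env <- new.env(parent = emptyenv())

# 12x12 Timoshenko space-frame element in local axes (x axial).
timoshenko_beam_matrix <- function(E, G, A, I, J, L, kappa = 0.886) {
  phi <- 12 * E * I / (kappa * G * A * L^2)
  k11 <- 12 * E * I / (L^3 * (1 + phi))
  k12 <- 6 * E * I / (L^2 * (1 + phi))
  k22 <- (4 + phi) * E * I / (L * (1 + phi))
  k23 <- (2 - phi) * E * I / (L * (1 + phi))
  ka <- E * A / L
  kt <- G * J / L
  K <- matrix(0, 12, 12)
  K[1, 1] <- K[7, 7] <- ka; K[1, 7] <- K[7, 1] <- -ka
  K[4, 4] <- K[10, 10] <- kt; K[4, 10] <- K[10, 4] <- -kt
  idx <- c(2, 6, 8, 12)
  K[idx, idx] <- K[idx, idx] +
    matrix(c(k11, k12, -k11, k12, k12, k22, -k12, k23,
             -k11, -k12, k11, -k12, k12, k23, -k12, k22), 4, 4, byrow = TRUE)
  idx <- c(3, 5, 9, 11)
  K[idx, idx] <- K[idx, idx] +
    matrix(c(k11, -k12, -k11, -k12, -k12, k22, k12, k23,
             -k11, k12, k11, k12, -k12, k23, k12, k22), 4, 4, byrow = TRUE)
  K
}

beam_frame_transform <- function(axis) {
  ex <- axis / sqrt(sum(axis^2))
  ref <- if (abs(ex[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  ey <- ref - sum(ref * ex) * ex
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2], ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- rbind(ex, ey, ez)
  T12 <- matrix(0, 12, 12)
  for (b in 0:3) T12[b * 3 + 1:3, b * 3 + 1:3] <- R
  T12
}

#' Elongated Kelvin-cell geometry
#'
#' Uniform elongation of the regular tetrakaidecahedron along the rise axis
#' gives a one-parameter cell shape: aspect ratio `R = H/D = tan(theta)`
#' with inclined strut length `L`, horizontal strut length
#' `b = sqrt(2) L cos(theta)`, cell width `D = 4 L cos(theta)` and height
#' `H = 4 L sin(theta)`. Circular struts of radius `r` give relative
#' density `rho = pi r^2 (2 + sqrt(2) cos(theta)) /
#' (8 L^2 cos(theta)^2 sin(theta))`, from which `r^2/L^2` is solved for a
#' target porosity.
#'
#' @param R aspect ratio `>= 1`.
#' @param porosity cell porosity in `(0, 1)`.
#' @param E0 solid-phase Young's modulus (MPa).
#' @param nu0 solid-phase Poisson ratio.
#' @return object of class `kelvin_cell_params` with fields `theta`, `L`,
#'   `b`, `r`, `H`, `D`, `A`, `I`, `J`, `E0`, `nu0`, `relative_density`.
#' @export
kelvin_cell_params <- function(R, porosity, E0, nu0 = 0.3) {
  if (R > 1 - 1e-9 && R < 1) R <- 1  # guard tan/atan round-trip noise
  stopifnot(R >= 1, porosity > 0, porosity < 1, E0 > 0)
  theta <- atan(R)
  L <- 1
  rho <- 1 - porosity
  r2 <- rho * 8 * cos(theta)^2 * sin(theta) / (pi * (2 + sqrt(2) * cos(theta)))
  r <- sqrt(r2) * L
  if (r / L > 0.5)
    stop(sprintf("porosity %.2f too low for the slender-strut cell (r/L = %.2f > 0.5)",
                 porosity, r / L))
  structure(list(theta = theta, L = L, b = sqrt(2) * L * cos(theta), r = r,
                 H = 4 * L * sin(theta), D = 4 * L * cos(theta),
                 A = pi * r^2, I = pi * r^4 / 4, J = pi * r^4 / 2,
                 E0 = E0, nu0 = nu0, relative_density = rho),
            class = "kelvin_cell_params")
}

# Precompute the 24 transformed beam stiffnesses and node positions of the
# period box for a given cell.
kelvin_frame_elements <- function(p) {
  gr <- kelvin_cell_graph()
  scale <- c(p$D / 4, p$D / 4, p$H / 4)
  X <- sweep(gr$nodes, 2, scale, "*")
  G0 <- p$E0 / (2 * (1 + p$nu0))
  ne <- nrow(gr$edges)
  Ks <- vector("list", ne)
  info <- vector("list", ne)
  for (e in seq_len(ne)) {
    i <- gr$edges[e, 1]; j <- gr$edges[e, 2]
    xi <- X[i, ]
    xj <- X[j, ] + gr$edges[e, 3:5] * scale
    dx <- xj - xi
    T12 <- beam_frame_transform(dx)
    Ks[[e]] <- crossprod(T12, timoshenko_beam_matrix(
      p$E0, G0, p$A, p$I, p$J, sqrt(sum(dx^2)))) %*% T12
    info[[e]] <- list(i = i, j = j, xi = xi, xj = xj)
  }
  list(Ks = Ks, info = info, V = prod(4 * scale), ndof = 72)
}

frame_strain_energy <- function(fe, w, eps) {
  Et <- 0
  for (e in seq_along(fe$Ks)) {
    a <- fe$info[[e]]
    d <- numeric(12)
    d[1:6] <- w[(a$i - 1) * 6 + 1:6]
    d[7:12] <- w[(a$j - 1) * 6 + 1:6]
    d[1:3] <- d[1:3] + eps %*% a$xi
    d[7:9] <- d[7:9] + eps %*% a$xj
    Et <- Et + 0.5 * sum(d * (fe$Ks[[e]] %*% d))
  }
  Et
}

# Symmetry-adapted mode shapes of the Kelvin frame under macroscopic strain
# (see the methods vignette for the derivation). Node roles:
# square-face vertices with x offset: 5(+),6(-),7(-),8(+)
# square-face vertices with y offset: 1(+),2(-),11(-),12(+)
# x-column mid nodes: 9(z+),10(z-); y-column mid nodes: 3(z+),4(z-)
kelvin_mode_bases <- function() {
  cache <- get0(".kelvin_bases", envir = .hapcage_env)
  if (!is.null(cache)) return(cache)
  set <- function(v, node, dof, val) { v[(node - 1) * 6 + dof] <- val; v }
  B <- function() numeric(72)
  xoff <- list(c(5, 1), c(6, -1), c(7, -1), c(8, 1))
  yoff <- list(c(1, 1), c(2, -1), c(11, -1), c(12, 1))
  xmid <- list(c(9, 1), c(10, -1))
  ymid <- list(c(3, 1), c(4, -1))
  bv <- list()
  v <- B(); for (q in xoff) v <- set(v, q[1], 1, q[2]); bv$px <- v
  v <- B(); for (q in yoff) v <- set(v, q[1], 2, q[2]); bv$py <- v
  v <- B(); for (q in xmid) v <- set(v, q[1], 3, q[2]); bv$dzx <- v
  v <- B(); for (q in ymid) v <- set(v, q[1], 3, q[2]); bv$dzy <- v
  v <- B(); for (q in xmid) v <- set(v, q[1], 1, q[2]); bv$e1 <- v
  v <- B(); for (q in ymid) v <- set(v, q[1], 1, -q[2]); bv$e2 <- v
  v <- B(); for (q in xoff) v <- set(v, q[1], 3, q[2]); bv$f13 <- v
  v <- B(); for (q in yoff) v <- set(v, q[1], 5, 1); bv$psi1 <- v
  v <- B(); for (q in c(xmid, ymid)) v <- set(v, q[1], 5, 1); bv$psi2 <- v
  v <- B(); for (q in xoff) v <- set(v, q[1], 5, 1); bv$psi3 <- v
  v <- B()
  for (q in yoff) v <- set(v, q[1], 1, -q[2])
  for (q in xoff) v <- set(v, q[1], 2, -q[2])
  bv$g <- v
  v <- B()
  for (q in yoff) v <- set(v, q[1], 6, -1)
  for (q in xoff) v <- set(v, q[1], 6, 1)
  bv$chi <- v
  v <- B(); for (q in c(xmid, ymid)) v <- set(v, q[1], 6, 1); bv$chim <- v
  out <- list(normal = cbind(bv$px, bv$py, bv$dzx, bv$dzy),
              shear13 = cbind(bv$e1, bv$e2, bv$f13, bv$psi1, bv$psi2, bv$psi3),
              shear12 = cbind(bv$g, bv$chi, bv$chim))
  assign(".kelvin_bases", out, envir = .hapcage_env)
  out
}

# minimize the reduced quadratic; returns the energy density numerator
kelvin_reduced_energy <- function(fe, Bm, eps) {
  k <- ncol(Bm)
  zero3 <- matrix(0, 3, 3)
  E00 <- frame_strain_energy(fe, numeric(72), eps)
  g <- numeric(k)
  H <- matrix(0, k, k)
  Ei <- numeric(k)
  for (i in seq_len(k)) {
    Ei[i] <- frame_strain_energy(fe, Bm[, i], zero3)
    H[i, i] <- 2 * Ei[i]
    g[i] <- frame_strain_energy(fe, Bm[, i], eps) - E00 - Ei[i]
  }
  if (k > 1) for (i in 2:k) for (j in seq_len(i - 1)) {
    Eij <- frame_strain_energy(fe, Bm[, i] + Bm[, j], zero3)
    H[i, j] <- H[j, i] <- Eij - Ei[i] - Ei[j]
  }
  alpha <- -solve(H, g)
  frame_strain_energy(fe, as.numeric(Bm %*% alpha), eps)
}

#' Transversely isotropic constants of the elongated Kelvin foam cell
#'
#' Analytic (symmetry-reduced) solution of the periodic Timoshenko strut
#' frame of the elongated tetrakaidecahedron: under each macroscopic strain
#' mode the nodal displacements reduce by symmetry to at most six scalar
#' amplitudes (in-plane square-face expansions, mid-node shifts, and three
#' joint-rotation amplitudes for axial shear), which are solved in closed
#' form; see the methods vignette. Moduli scale linearly with `E0`.
#'
#' @param R cell aspect ratio (`H/D = tan(theta)`), `>= 1`.
#' @param porosity cell porosity in `(0, 1)`; an error is raised when the
#'   implied strut radius violates the slender-strut assumption
#'   (`r/L > 0.5`).
#' @param E0 solid-phase modulus (MPa).
#' @param nu0 solid-phase Poisson ratio.
#' @return list with `E_axial`, `E_trans`, `nu_axial`, `nu_trans`,
#'   `G_axial` (MPa where applicable), the 6x6 stiffness `C`, and the cell
#'   geometry (`theta`, `r_over_L`, `relative_density`).
#' @export
kelvin_cell_constants <- function(R, porosity, E0, nu0 = 0.3) {
  p <- kelvin_cell_params(R, porosity, E0, nu0)
  fe <- kelvin_frame_elements(p)
  bases <- kelvin_mode_bases()
  epsN <- function(a, b, c_) diag(c(a, b, c_))
  Wn <- function(a, b, c_)
    kelvin_reduced_energy(fe, bases$normal, epsN(a, b, c_)) / fe$V
  C <- matrix(0, 6, 6)
  W100 <- Wn(1, 0, 0); W010 <- Wn(0, 1, 0); W001 <- Wn(0, 0, 1)
  C[1, 1] <- 2 * W100; C[2, 2] <- 2 * W010; C[3, 3] <- 2 * W001
  C[1, 2] <- C[2, 1] <- Wn(1, 1, 0) - W100 - W010
  C[1, 3] <- C[3, 1] <- Wn(1, 0, 1) - W100 - W001
  C[2, 3] <- C[3, 2] <- Wn(0, 1, 1) - W010 - W001
  e13 <- matrix(0, 3, 3); e13[1, 3] <- e13[3, 1] <- 0.5
  C[5, 5] <- C[4, 4] <- 2 * kelvin_reduced_energy(fe, bases$shear13, e13) / fe$V
  e12 <- matrix(0, 3, 3); e12[1, 2] <- e12[2, 1] <- 0.5
  C[6, 6] <- 2 * kelvin_reduced_energy(fe, bases$shear12, e12) / fe$V
  S <- solve(C)
  list(E_axial = 1 / S[3, 3], E_trans = 1 / S[1, 1],
       nu_axial = -S[1, 3] / S[3, 3], nu_trans = -S[1, 2] / S[1, 1],
       G_axial = 1 / S[4, 4], C = C,
       theta = p$theta, r_over_L = p$r / p$L,
       relative_density = p$relative_density)
}

#' Numeric periodic beam-frame homogenization of the Kelvin cell
#'
#' Independent cross-check for [kelvin_cell_constants()]: assembles the full
#' 12-node, 24-strut periodic Timoshenko frame (72 DOF, no symmetry
#' assumptions), solves the fluctuation problem for the six unit macroscopic
#' strains plus all pairwise combinations, and recovers the effective
#' stiffness from the energy densities.
#'
#' @param params a [kelvin_cell_params] object.
#' @return same fields as [kelvin_cell_constants()].
#' @export
beam_frame_unit_cell_oracle <- function(params) {
  stopifnot(inherits(params, "kelvin_cell_params"))
  fe <- kelvin_frame_elements(params)
  ndof <- fe$ndof
  K <- matrix(0, ndof, ndof)
  for (e in seq_along(fe$Ks)) {
    a <- fe$info[[e]]
    di <- (a$i - 1) * 6 + 1:6
    dj <- (a$j - 1) * 6 + 1:6
    Ke <- fe$Ks[[e]]
    K[di, di] <- K[di, di] + Ke[1:6, 1:6]
    K[di, dj] <- K[di, dj] + Ke[1:6, 7:12]
    K[dj, di] <- K[dj, di] + Ke[7:12, 1:6]
    K[dj, dj] <- K[dj, dj] + Ke[7:12, 7:12]
  }
  keep <- setdiff(seq_len(ndof), 1:3)
  Kf <- K[keep, keep]
  solve_case <- function(eps) {
    f <- numeric(ndof)
    for (e in seq_along(fe$Ks)) {
      a <- fe$info[[e]]
      da <- numeric(12)
      da[1:3] <- eps %*% a$xi
      da[7:9] <- eps %*% a$xj
      fv <- fe$Ks[[e]] %*% da
      f[(a$i - 1) * 6 + 1:6] <- f[(a$i - 1) * 6 + 1:6] - fv[1:6]
      f[(a$j - 1) * 6 + 1:6] <- f[(a$j - 1) * 6 + 1:6] - fv[7:12]
    }
    if (max(abs(f)) == 0) return(frame_strain_energy(fe, numeric(ndof), eps) / fe$V)
    w <- numeric(ndof)
    sol <- tryCatch(solve(Kf, f[keep]), error = function(e)
      stop("singular beam frame system: ", conditionMessage(e)))
    w[keep] <- sol
    frame_strain_energy(fe, w, eps) / fe$V
  }
  cases <- list(diag(c(1, 0, 0)), diag(c(0, 1, 0)), diag(c(0, 0, 1)),
                matrix(c(0, 0, 0, 0, 0, .5, 0, .5, 0), 3, 3),
                matrix(c(0, 0, .5, 0, 0, 0, .5, 0, 0), 3, 3),
                matrix(c(0, .5, 0, .5, 0, 0, 0, 0, 0), 3, 3))
  W <- vapply(cases, solve_case, numeric(1))
  C <- diag(2 * W)
  for (i in 1:5) for (j in (i + 1):6) {
    Wij <- solve_case(cases[[i]] + cases[[j]])
    C[i, j] <- C[j, i] <- Wij - W[i] - W[j]
  }
  S <- solve(C)
  list(E_axial = 1 / S[3, 3], E_trans = 1 / S[1, 1],
       nu_axial = -S[1, 3] / S[3, 3], nu_trans = -S[1, 2] / S[1, 1],
       G_axial = 1 / S[4, 4], C = C,
       theta = params$theta, r_over_L = params$r / params$L,
       relative_density = params$relative_density)
}

# Vectorized Kelvin constants via a cached (theta, rho) interpolation grid;
# constants scale linearly in E0, so the grid is built at E0 = 1.
kelvin_constants_interp <- function(R, porosity, E0, nu0 = 0.3,
                                    n_theta = 24, n_rho = 28) {
  key <- sprintf(".kelvin_grid_%0.4f", nu0)
  grid <- get0(key, envir = .hapcage_env)
  if (is.null(grid)) {
    thetas <- atan(seq(1, 10.5, length.out = n_theta))
    rhos <- exp(seq(log(0.01), log(0.55), length.out = n_rho))
    vals <- array(NA_real_, c(n_theta, n_rho, 5))
    for (i in seq_len(n_theta)) for (j in seq_len(n_rho)) {
      Rij <- tan(thetas[i])
      kc <- tryCatch(kelvin_cell_constants(Rij, 1 - rhos[j], 1, nu0),
                     error = function(e) NULL)
      if (!is.null(kc))
        vals[i, j, ] <- c(kc$E_axial, kc$E_trans, kc$nu_axial, kc$nu_trans,
                          kc$G_axial)
    }
    grid <- list(thetas = thetas, rhos = rhos, vals = vals)
    assign(key, grid, envir = .hapcage_env)
  }
  theta <- atan(pmin(pmax(R, 1), 10.4))
  rho <- pmin(pmax(1 - porosity, min(grid$rhos)), max(grid$rhos))
  it <- findInterval(theta, grid$thetas, all.inside = TRUE)
  ir <- findInterval(rho, grid$rhos, all.inside = TRUE)
  tt <- (theta - grid$thetas[it]) /
    (grid$thetas[it + 1] - grid$thetas[it])
  rr <- (rho - grid$rhos[ir]) / (grid$rhos[ir + 1] - grid$rhos[ir])
  out <- matrix(0, length(R), 5)
  for (kk in 1:5) {
    v00 <- grid$vals[cbind(it, ir, kk)]
    v10 <- grid$vals[cbind(it + 1, ir, kk)]
    v01 <- grid$vals[cbind(it, ir + 1, kk)]
    v11 <- grid$vals[cbind(it + 1, ir + 1, kk)]
    out[, kk] <- (1 - tt) * (1 - rr) * v00 + tt * (1 - rr) * v10 +
      (1 - tt) * rr * v01 + tt * rr * v11
  }
  # moduli scale with E0; Poisson ratios do not
  list(E_axial = out[, 1] * E0, E_trans = out[, 2] * E0,
       nu_axial = out[, 3], nu_trans = out[, 4], G_axial = out[, 5] * E0)
}
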