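# Linear-static finite element solver on tetrahedral meshes with
# per-element anisotropic materials, rigid kinematic coupling to a
# reference point, and the damage / fixation / macroscopic stiffness
# post-processing.

#' Physiological load case
#'
#' Standing: vertical axial load of 500 N. Forward flexion: 1175 N combined
#' with a transversally directed bending moment (7.5 N m by default; the
#' magnitude is configurable, and can be set to 7.5 N mm to reproduce a
#' literal millinewton-metre reading).
#'
#' @param name `"standing"` or `"flexion"`.
#' @param axial_force_N axial force magnitude (applied along -z).
#' @param moment_Nm bending moment magnitude about the transverse x axis
#'   (flexion only).
#' @return object of class `load_case` (forces in N, moments in N mm).
#' @export
load_case <- function(name = c("standing", "flexion"),
                      axial_force_N = NULL, moment_Nm = NULL) {
  name <- match.arg(name)
  if (is.null(axial_force_N)) axial_force_N <- if (name == "standing") 500 else 1175
  if (is.null(moment_Nm)) moment_Nm <- if (name == "standing") 0 else 7.5
  stopifnot(is.finite(axial_force_N), is.finite(moment_Nm))
  # forward flexion: moment about -x tilts the superior vertebra toward
  # the anterior (+y) side, compressing the anterior scaffold
  structure(list(name = name, force = c(0, 0, -axial_force_N),
                 moment = c(-moment_Nm * 1000, 0, 0)),  # N mm
            class = "load_case")
}

#' Damage thresholds
#'
#' @param hap_tension,hap_compression dense-material strength (MPa) used
#'   for microstructured scaffolds; homogenized scaffolds use the
#'   [macroscopic_strength()] values at the scaffold porosity.
#' @param trabecular_strain_limit compressive principal strain magnitude
#'   above which trabecular bone counts as damaged (default 0.84%).
#' @param sigma_yield fixation (Ti6Al4V) yield stress, MPa.
#' @return object of class `damage_thresholds`.
#' @export
damage_thresholds <- function(hap_tension = 100, hap_compression = 350,
                              trabecular_strain_limit = 0.0084,
                              sigma_yield = 795) {
  stopifnot(hap_tension > 0, hap_compression > 0,
            trabecular_strain_limit > 0, sigma_yield > 0)
  structure(list(hap_tension = hap_tension,
                 hap_compression = hap_compression,
                 trabecular_strain_limit = trabecular_strain_limit,
                 sigma_yield = sigma_yield), class = "damage_thresholds")
}

#' Linear-static solve of a tetrahedral model
#'
#' Constant-strain tetrahedra, sparse symmetric assembly and Cholesky
#' solve. Dirichlet supports fix nodes; an optional rigid kinematic
#' coupling ties a slave node set to a 6-DOF reference point
#' (`u_s = u_rp + theta x r_s`), at which the load is applied. Tied
#' interfaces are realized by shared nodes (node merging).
#'
#' @param mesh a [tet_mesh].
#' @param materials 21 x n_elements packed Voigt stiffnesses (MPa), e.g.
#'   from [nearest_voxel_assign()].
#' @param fixed_nodes integer node ids with all DOFs fixed.
#' @param coupling `NULL`, or list with `ref_point` (length-3, outside the
#'   mesh) and `nodes` (slave node ids).
#' @param load list with `force` (N) and `moment` (N mm) applied at the
#'   reference point, or a [load_case]; ignored if no coupling is given.
#' @param nodal_forces optional 3 x n or dense vector of nodal loads.
#' @param prescribed optional inhomogeneous Dirichlet data: list with
#'   `dofs` (global DOF indices, `3*(node-1)+component`) and `values`.
#' @return object of class `fe_result`: displacements `u` (n x 3),
#'   `rp_disp`, `rp_rot`, element `strain` and `stress` (6 x m), principal
#'   values, element volumes, and the global equilibrium residual.
#' @export
solve_linear_static <- function(mesh, materials, fixed_nodes,
                                coupling = NULL, load = NULL,
                                nodal_forces = NULL, prescribed = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  if (length(fixed_nodes) == 0 && is.null(coupling) && is.null(prescribed))
    stop("model has unconstrained rigid-body modes")
  asm <- .tet_assemble(mesh$nodes, mesh$elems, materials)
  K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                            dims = c(ndof, ndof))

  slave <- if (!is.null(coupling)) coupling$nodes else integer(0)
  if (length(intersect(slave, fixed_nodes)))
    stop("coupled nodes cannot also be fixed")
  fixed_dofs <- as.vector(outer(3 * (fixed_nodes - 1), 1:3, "+"))
  slave_dofs <- as.vector(outer(3 * (slave - 1), 1:3, "+"))
  up <- numeric(ndof)
  pres_dofs <- integer(0)
  if (!is.null(prescribed)) {
    pres_dofs <- prescribed$dofs
    up[pres_dofs] <- prescribed$values
  }
  free_dofs <- setdiff(seq_len(ndof), c(fixed_dofs, slave_dofs, pres_dofs))
  nfree <- length(free_dofs)
  nq <- nfree + if (!is.null(coupling)) 6L else 0L

  ti <- free_dofs
  tj <- seq_len(nfree)
  tx <- rep(1, nfree)
  if (!is.null(coupling)) {
    rp <- coupling$ref_point
    r <- sweep(mesh$nodes[slave, , drop = FALSE], 2, rp, "-")
    # u_s = u_rp + theta x r:
    # u_x = U1 + T2 r_z - T3 r_y ; u_y = U2 + T3 r_x - T1 r_z
    # u_z = U3 + T1 r_y - T2 r_x
    ns <- length(slave)
    sd <- 3 * (slave - 1)
    ti <- c(ti, sd + 1, sd + 1, sd + 1, sd + 2, sd + 2, sd + 2,
            sd + 3, sd + 3, sd + 3)
    qU <- nfree
    tj <- c(tj, rep(qU + 1, ns), rep(qU + 5, ns), rep(qU + 6, ns),
            rep(qU + 2, ns), rep(qU + 6, ns), rep(qU + 4, ns),
            rep(qU + 3, ns), rep(qU + 4, ns), rep(qU + 5, ns))
    tx <- c(tx, rep(1, ns), r[, 3], -r[, 2],
            rep(1, ns), r[, 1], -r[, 3],
            rep(1, ns), r[, 2], -r[, 1])
  }
  Tm <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, nq))
  Kr <- Matrix::forceSymmetric(Matrix::crossprod(Tm, K %*% Tm))

  f_full <- numeric(ndof)
  if (!is.null(nodal_forces)) {
    nf <- if (is.matrix(nodal_forces)) as.numeric(t(nodal_forces)) else nodal_forces
    f_full <- f_full + nf
  }
  if (length(pres_dofs)) f_full_eff <- f_full - as.numeric(K %*% up)
  else f_full_eff <- f_full
  fr <- as.numeric(Matrix::crossprod(Tm, f_full_eff))
  if (!is.null(coupling)) {
    if (inherits(load, "load_case")) load <- list(force = load$force,
                                                  moment = load$moment)
    if (is.null(load)) load <- list(force = c(0, 0, 0), moment = c(0, 0, 0))
    fr[nfree + 1:3] <- fr[nfree + 1:3] + load$force
    fr[nfree + 4:6] <- fr[nfree + 4:6] + load$moment
  }
  ch <- tryCatch(Matrix::Cholesky(Kr, LDL = FALSE),
                 error = function(e)
                   stop("singular system (unconstrained modes?): ",
                        conditionMessage(e)))
  q <- as.numeric(Matrix::solve(ch, fr))
  u <- as.numeric(Tm %*% q) + up

  strain <- .tet_strains(mesh$nodes, mesh$elems, u)
  stress <- stress_from_strain(materials, strain)
  pe <- .eig_sym3_batch(strain_to_tensor(strain))
  ps <- .eig_sym3_batch(stress)  # stress rows already tensor components

  # equilibrium on the unconstrained DOFs: K_red q must balance the applied
  # reduced loads; reaction forces live on the fixed DOFs
  rfree <- as.numeric(Kr %*% q) - fr
  eq_resid <- sqrt(sum(rfree^2)) / max(sqrt(sum(fr^2)), 1e-30)
  reactions <- matrix(as.numeric(K %*% u - f_full), nrow = 3)

  structure(list(
    u = matrix(u, ncol = 3, byrow = TRUE),
    rp_disp = if (!is.null(coupling)) q[nfree + 1:3] else NULL,
    rp_rot = if (!is.null(coupling)) q[nfree + 4:6] else NULL,
    strain = strain, stress = stress,
    principal_stress = ps$values, principal_strain = pe$values,
    volume = abs(asm$volume), equilibrium_residual = eq_resid,
    reactions = t(reactions), load = load), class = "fe_result")
}

# sigma = C eps, packed symmetric C (21 x m), engineering strains
stress_from_strain <- function(C21, strain) {
  pair <- matrix(0L, 6, 6)
  k <- 0
  for (j in 1:6) for (i in 1:j) { k <- k + 1; pair[i, j] <- pair[j, i] <- k }
  out <- matrix(0, 6, ncol(strain))
  for (i in 1:6) {
    acc <- 0
    for (j in 1:6) acc <- acc + C21[pair[i, j], ] * strain[j, ]
    out[i, ] <- acc
  }
  out
}

# engineering strain 6-vector -> tensor components (halve the shears) for
# principal value extraction
strain_to_tensor <- function(strain) {
  t_ <- strain
  t_[4:6, ] <- t_[4:6, ] / 2
  t_
}

von_mises <- function(stress) {
  s11 <- stress[1, ]; s22 <- stress[2, ]; s33 <- stress[3, ]
  s23 <- stress[4, ]; s13 <- stress[5, ]; s12 <- stress[6, ]
  sqrt(0.5 * ((s11 - s22)^2 + (s22 - s33)^2 + (s33 - s11)^2) +
         3 * (s12^2 + s13^2 + s23^2))
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf("fe_result: %d nodes, %d elements, equilibrium residual %.2e\n",
              nrow(x$u), ncol(x$strain), x$equilibrium_residual))
  if (!is.null(x$rp_disp))
    cat(sprintf("  reference point: u = (%.4g, %.4g, %.4g) mm\n",
                x$rp_disp[1], x$rp_disp[2], x$rp_disp[3]))
  invisible(x)
}

#' Failed scaffold volume percentage
#'
#' Volume-weighted percentage of elements whose maximum principal stress
#' exceeds the tensile threshold (`mode = "tension"`), whose minimum
#' principal stress is below minus the compressive threshold
#' (`"compression"`), or either (`"either"`).
#'
#' @param result an `fe_result`.
#' @param elements integer element ids of the scaffold.
#' @param tension_limit,compression_limit thresholds (MPa).
#' @param mode `"tension"`, `"compression"` or `"either"`.
#' @return percentage in `[0, 100]`.
#' @export
failed_volume <- function(result, elements, tension_limit, compression_limit,
                          mode = c("either", "tension", "compression")) {
  mode <- match.arg(mode)
  if (length(elements) == 0) stop("empty scaffold element set")
  smax <- result$principal_stress[3, elements]
  smin <- result$principal_stress[1, elements]
  vol <- result$volume[elements]
  fail_t <- smax > tension_limit
  fail_c <- smin < -compression_limit
  fail <- switch(mode, tension = fail_t, compression = fail_c,
                 either = fail_t | fail_c)
  100 * sum(vol[fail]) / sum(vol)
}

#' Damaged trabecular bone volume percentage
#'
#' Volume fraction of trabecular elements whose minimum principal strain is
#' below `-limit` (compressive exceedance of the trabecular yield strain).
#'
#' @param result an `fe_result`.
#' @param elements trabecular element ids.
#' @param limit strain magnitude (default 0.84%).
#' @return percentage in `[0, 100]`.
#' @export
damaged_trabecular_volume <- function(result, elements, limit = 0.0084) {
  if (length(elements) == 0) return(0)
  emin <- result$principal_strain[1, elements]
  vol <- result$volume[elements]
  100 * sum(vol[emin < -limit]) / sum(vol)
}

#' Fixation system metrics
#'
#' Yield safety ratio (yield stress over the maximum von Mises stress in
#' the central portion of the rods), minimum / maximum axial microstrains
#' per rod, and the axial load share transmitted through a planar cut of
#' the rods.
#'
#' @param result an `fe_result`.
#' @param mesh the [tet_mesh].
#' @param rod_elements list of integer element-id vectors, one per rod.
#' @param applied_axial_force total applied axial force (N).
#' @param sigma_yield yield stress (MPa; default 795).
#' @param central_fraction fraction of the rod length counted as central.
#' @return list with `yield_ratio`, per-rod `microstrain_min`,
#'   `microstrain_max`, `rod_force_N` and `load_share_pct`.
#' @export
fixation_metrics <- function(result, mesh, rod_elements, applied_axial_force,
                             sigma_yield = 795, central_fraction = 1 / 3) {
  stopifnot(length(rod_elements) >= 1)
  cen <- element_centroids(mesh)
  rod_force <- numeric(length(rod_elements))
  ms_min <- ms_max <- numeric(length(rod_elements))
  vm_max <- 0
  for (k in seq_along(rod_elements)) {
    els <- rod_elements[[k]]
    if (length(els) == 0) stop("cut plane misses rod ", k)
    z <- cen[els, 3]
    zmid <- (min(z) + max(z)) / 2
    halfspan <- (max(z) - min(z)) / 2
    central <- els[abs(z - zmid) <= central_fraction * halfspan]
    if (length(central) == 0) central <- els
    vm_max <- max(vm_max, von_mises(result$stress[, central, drop = FALSE]))
    ezz <- result$strain[3, central] * 1e6
    ms_min[k] <- min(ezz)
    ms_max[k] <- max(ezz)
    # axial force through a thin slab at mid-height: sum sigma_zz * dA,
    # with dA = element volume / slab thickness
    slab_h <- max(2 * attr(mesh, "cell_mm")[3] %||% 2, 1e-3)
    slab <- els[abs(z - zmid) <= slab_h / 2]
    if (length(slab) == 0) slab <- central
    rod_force[k] <- sum(result$stress[3, slab] * result$volume[slab]) /
      (max(cen[slab, 3]) - min(cen[slab, 3]) + slab_h / 2)
  }
  yr <- if (vm_max > 0) sigma_yield / vm_max else Inf
  list(yield_ratio = min(yr, 1e6),
       microstrain_min = ms_min, microstrain_max = ms_max,
       rod_force_N = rod_force,
       load_share_pct = 100 * sum(abs(rod_force)) / abs(applied_axial_force))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Macroscopic stiffness and rotation from the reference point
#'
#' Stiffness is the applied axial force divided by the reference-point
#' axial displacement (kN/mm); the rotation angle comes from the reference
#' point's rotational degrees of freedom (degrees).
#'
#' @param result an `fe_result` solved with a kinematic coupling.
#' @param load the applied [load_case] (or list with `force`).
#' @return list with `stiffness_kN_mm` and `rotation_deg`.
#' @export
macroscopic_response <- function(result, load) {
  if (is.null(result$rp_disp)) stop("no reference point in this solve")
  if (inherits(load, "load_case")) fz <- load$force[3] else fz <- load$force[3]
  uz <- result$rp_disp[3]
  if (abs(uz) < 1e-14) stop("zero reference-point displacement")
  list(stiffness_kN_mm = abs(fz / uz) / 1000,
       rotation_deg = max(abs(result$rp_rot)) * 180 / pi)
}
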