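# Per-voxel elasticity fields and mapping onto tetrahedral meshes.

#' Build a per-voxel anisotropic elasticity field for bone
#'
#' Combines porosity and fabric into Voigt stiffness tensors, voxel by
#' voxel. Cortical voxels with resolved directions get the
#' cylindrical-inclusion Mori-Tanaka stiffness (cylinder axis along the
#' stiff GST axis `e1`); flagged cortical voxels fall back to the spherical
#' Eshelby model with their own porosity. Trabecular voxels get the
#' transversely isotropic elongated Kelvin-cell foam stiffness with aspect
#' ratio `R = lambda3/lambda1` (capped); flagged trabecular voxels use an
#' isotropic reduction of the equiaxed (`R = 1`) cell. Cortical stiffness is
#' interpolated from a porosity lookup table; Kelvin constants from a
#' `(theta, density)` table (both dense enough that the interpolation error
#' is far below model uncertainty).
#'
#' @param pf a [porosity_field].
#' @param fabric_cortical,fabric_trabecular `fabric_field`s from
#'   [gradient_structure_tensor()] run separately on each tissue label.
#' @param E0_trab solid-phase modulus of trabecular struts (MPa; default
#'   13 GPa, a typical tissue-level value).
#' @param cortical a [cortical_model_params].
#' @param nu0_trab strut Poisson ratio.
#' @param r_max aspect-ratio cap.
#' @return object of class `elasticity_field`: `index` (array, 0 where no
#'   tissue, else column into `C21`), packed stiffnesses `C21` (21 x n,
#'   MPa, world axes), `tissue` per column, and grid metadata.
#' @export
map_bone_properties <- function(pf, fabric_cortical, fabric_trabecular,
                                E0_trab = 13000,
                                cortical = cortical_model_params(),
                                nu0_trab = 0.3, r_max = 10) {
  stopifnot(inherits(pf, "porosity_field"))
  d <- dim(pf$porosity)
  cort_idx <- which(pf$tissue == 1L)
  trab_idx <- which(pf$tissue == 2L)
  n <- length(cort_idx) + length(trab_idx)
  C21 <- matrix(0, 21, n)
  tissue <- integer(n)
  index <- array(0L, d)
  col <- 0L

  # --- cortical: porosity lookup tables ------------------------------------
  if (length(cort_idx)) {
    phi <- pmin(pmax(pf$porosity[cort_idx], 0), 0.5)
    phig <- seq(0, 0.5, length.out = 65)
    Ccyl <- vapply(phig, function(p) pack_voigt(cortical_stiffness(p, cortical)),
                   numeric(21))
    Csph <- vapply(phig, function(p)
      pack_voigt(isotropic_fallback_stiffness(p, cortical)), numeric(21))
    interp_cols <- function(tab, x, xg) {
      i <- findInterval(x, xg, all.inside = TRUE)
      w <- (x - xg[i]) / (xg[i + 1] - xg[i])
      tab[, i, drop = FALSE] * rep(1 - w, each = 21) +
        tab[, i + 1, drop = FALSE] * rep(w, each = 21)
    }
    flag <- fabric_cortical$isotropic[cort_idx]
    flag[is.na(flag)] <- TRUE
    Cl <- interp_cols(Ccyl, phi, phig)
    Cl[, flag] <- interp_cols(Csph, phi[flag], phig)
    # rotate resolved voxels: local 3-axis -> world e1 (stiff axis)
    res <- which(!flag)
    if (length(res)) {
      rows <- match(cort_idx[res], fabric_cortical$voxel_index)
      Q <- fabric_basis(fabric_cortical, rows)
      Cl[, res] <- .rotate_stiffness_batch(Cl[, res, drop = FALSE], Q)
    }
    cols <- col + seq_along(cort_idx)
    C21[, cols] <- Cl
    tissue[cols] <- 1L
    index[cort_idx] <- cols
    col <- col + length(cort_idx)
  }

  # --- trabecular: Kelvin foam ---------------------------------------------
  if (length(trab_idx)) {
    phi <- pmin(pmax(pf$porosity[trab_idx], 0.5), 0.97)
    flag <- fabric_trabecular$isotropic[trab_idx]
    flag[is.na(flag)] <- TRUE
    Rv <- fabric_trabecular$R[trab_idx]
    Rv[is.na(Rv) | flag] <- 1
    Rv <- pmin(pmax(Rv, 1), r_max)
    kc <- kelvin_constants_interp(Rv, phi, E0_trab, nu0_trab)
    Cl <- ti_stiffness(kc$E_axial, kc$E_trans, kc$nu_axial, kc$nu_trans,
                       kc$G_axial)
    # flagged voxels: isotropic reduction of the R = 1 cell
    if (any(flag)) {
      Ei <- kc$E_axial[flag]
      nui <- pmin(pmax(kc$nu_trans[flag], 0.05), 0.45)
      Cl[, flag] <- iso_stiffness_packed(Ei, nui)
    }
    res <- which(!flag)
    if (length(res)) {
      rows <- match(trab_idx[res], fabric_trabecular$voxel_index)
      Q <- fabric_basis(fabric_trabecular, rows)
      Cl[, res] <- .rotate_stiffness_batch(Cl[, res, drop = FALSE], Q)
    }
    cols <- col + seq_along(trab_idx)
    C21[, cols] <- Cl
    tissue[cols] <- 2L
    index[trab_idx] <- cols
  }

  structure(list(index = index, C21 = C21, tissue = tissue,
                 spacing = pf$spacing, origin = pf$origin, dim = d),
            class = "elasticity_field")
}

# packed isotropic stiffness columns (vectorized)
iso_stiffness_packed <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  P <- matrix(0, 21, length(E))
  P[1, ] <- P[3, ] <- P[6, ] <- lam + 2 * mu
  P[2, ] <- P[4, ] <- P[5, ] <- lam
  P[10, ] <- P[15, ] <- P[21, ] <- mu
  P
}

# 9 x n rotation matrices with world columns (e2, e3, e1): local axis 3 is
# the stiff axis e1; handedness fixed.
fabric_basis <- function(fabric, rows) {
  e1 <- fabric$e1[rows, , drop = FALSE]
  e2 <- fabric$e2[rows, , drop = FALSE]
  e3 <- fabric$e3[rows, , drop = FALSE]
  # enforce right-handedness of (e2, e3, e1)
  cr <- cbind(e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
              e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
              e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  s <- sign(rowSums(cr * e1))
  s[s == 0] <- 1
  e1 <- e1 * s
  t(cbind(e2, e3, e1))  # 9 x n, columns stacked (e2, e3, e1)
}

#' @export
print.elasticity_field <- function(x, ...) {
  cat(sprintf("elasticity_field: %d voxels with tissue (%d cortical, %d trabecular)\n",
              ncol(x$C21), sum(x$tissue == 1), sum(x$tissue == 2)))
  invisible(x)
}

#' Nearest Voxel Strategy: assign voxel materials to elements
#'
#' Each element receives the stiffness of the voxel whose centre is nearest
#' to the element centroid (for the regular grid this is the rounded index;
#' exact half-way ties resolve to the lower index, hence the lowest linear
#' voxel index). Elements whose nearest voxel carries no tissue receive
#' `default_stiffness` and are counted in the `n_default` attribute.
#'
#' @param mesh a [tet_mesh].
#' @param field an `elasticity_field`.
#' @param default_stiffness 6x6 matrix for uncovered elements, or `NULL` to
#'   error when any element is uncovered.
#' @return 21 x n_elements packed stiffness matrix with attributes
#'   `n_default` and `default_elements`.
#' @export
nearest_voxel_assign <- function(mesh, field, default_stiffness = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(field, "elasticity_field"))
  if (ncol(field$C21) == 0) stop("empty elasticity field")
  cen <- element_centroids(mesh)
  d <- field$dim
  axis_index <- function(a) {
    q <- (cen[, a] - field$origin[a]) / field$spacing[a]
    pmin(pmax(ceiling(q - 0.5), 0), d[a] - 1) + 1
  }
  ijk <- cbind(axis_index(1), axis_index(2), axis_index(3))
  lin <- ijk[, 1] + d[1] * (ijk[, 2] - 1) + d[1] * d[2] * (ijk[, 3] - 1)
  colidx <- field$index[lin]
  uncovered <- which(colidx == 0)
  mats <- matrix(0, 21, nrow(mesh$elems))
  covered <- which(colidx > 0)
  mats[, covered] <- field$C21[, colidx[covered], drop = FALSE]
  if (length(uncovered)) {
    if (is.null(default_stiffness))
      stop(length(uncovered), " elements fall outside all labelled voxels; ",
           "supply default_stiffness")
    mats[, uncovered] <- pack_voigt(check_voigt(default_stiffness))
  }
  attr(mats, "n_default") <- length(uncovered)
  attr(mats, "default_elements") <- uncovered
  mats
}
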