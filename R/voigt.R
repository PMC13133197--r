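# Voigt convention used package-wide: order (11, 22, 33, 23, 13, 12),
# engineering shear strains, stiffnesses in MPa. Asserted at module
# boundaries via `check_voigt()`.

#' Isotropic stiffness matrix
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @return 6x6 Voigt stiffness (engineering shears).
#' @export
iso_stiffness <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3] <- C[1:3, 1:3] + lam
  C
}

#' Transversely isotropic stiffness from engineering constants
#'
#' Symmetry axis along local axis 3. `E_axial` is the modulus along the
#' axis, `E_trans` in the isotropy plane, `nu_axial` the contraction in the
#' plane under axial load (nu_31), `nu_trans` the in-plane ratio, `G_axial`
#' the axial shear modulus (13/23 planes). The in-plane shear modulus is
#' `E_trans / (2 (1 + nu_trans))`.
#'
#' @param E_axial,E_trans,nu_axial,nu_trans,G_axial engineering constants
#'   (vectorized; moduli in MPa).
#' @return a 6x6 matrix, or a 21 x n packed matrix when inputs have length
#'   n > 1 (upper triangle, column-major).
#' @export
ti_stiffness <- function(E_axial, E_trans, nu_axial, nu_trans, G_axial) {
  a <- 1 / E_trans                 # S11
  b <- -nu_trans / E_trans         # S12
  c_ <- -nu_axial / E_axial        # S13 (= S31)
  d <- 1 / E_axial                 # S33
  det <- (a - b) * (d * (a + b) - 2 * c_^2)
  C11 <- (a * d - c_^2) / det
  C12 <- (c_^2 - b * d) / det
  C13 <- -c_ * (a - b) / det
  C33 <- (a^2 - b^2) / det
  C44 <- G_axial
  C66 <- 1 / (2 * (a - b))
  n <- length(C11)
  if (n == 1) {
    C <- matrix(0, 6, 6)
    C[1, 1] <- C[2, 2] <- C11
    C[1, 2] <- C[2, 1] <- C12
    C[1, 3] <- C[3, 1] <- C[2, 3] <- C[3, 2] <- C13
    C[3, 3] <- C33
    C[4, 4] <- C[5, 5] <- C44
    C[6, 6] <- C66
    C
  } else {
    P <- matrix(0, 21, n)
    # packed upper-triangle order: (11,12,22,13,23,33,14..44,...)
    P[1, ] <- C11; P[2, ] <- C12; P[3, ] <- C11
    P[4, ] <- C13; P[5, ] <- C13; P[6, ] <- C33
    P[10, ] <- C44; P[15, ] <- C44; P[21, ] <- C66
    P
  }
}

#' Pack / unpack symmetric 6x6 Voigt matrices
#'
#' Column-major upper-triangle packing into 21 values, used for per-element
#' and per-voxel stiffness storage.
#'
#' @param C 6x6 symmetric matrix.
#' @param p length-21 packed vector.
#' @return `pack_voigt`: length-21 vector; `unpack_voigt`: 6x6 matrix.
#' @export
pack_voigt <- function(C) C[upper.tri(C, diag = TRUE)]

#' @rdname pack_voigt
#' @export
unpack_voigt <- function(p) {
  C <- matrix(0, 6, 6)
  C[upper.tri(C, diag = TRUE)] <- p
  C <- C + t(C) - diag(diag(C))
  C
}

check_voigt <- function(C, tol = 1e-6) {
  stopifnot(is.matrix(C), all(dim(C) == c(6, 6)))
  if (max(abs(C - t(C))) > tol * max(abs(C)))
    stop("stiffness matrix is not symmetric")
  invisible(C)
}

#' Rotate a Voigt stiffness matrix into another basis
#'
#' Standard fourth-order tensor rotation expressed on 6x6 engineering-Voigt
#' matrices (Bond transformation). `basis` columns are the local material
#' axes expressed in world coordinates; the result expresses the same
#' elasticity in world axes. Symmetry and positive definiteness are
#' preserved.
#'
#' @param C_local 6x6 stiffness in the local frame.
#' @param basis 3x3 orthonormal matrix (columns = local axes in world).
#' @return 6x6 stiffness in world axes.
#' @export
rotate_stiffness <- function(C_local, basis) {
  check_voigt(C_local)
  Q <- as.matrix(basis)
  if (max(abs(crossprod(Q) - diag(3))) > 1e-6)
    stop("basis is not orthonormal")
  out <- .rotate_stiffness_batch(matrix(pack_voigt(C_local), ncol = 1),
                                 matrix(as.numeric(Q), ncol = 1))
  unpack_voigt(out[, 1])
}

# Eshelby tensor (interior point, isotropic matrix, Poisson ratio nu) as a
# Voigt operator on engineering strains. shape: "sphere" or "cylinder"
# (infinite circular cylinder along axis 3).
eshelby_voigt <- function(nu, shape = c("sphere", "cylinder")) {
  shape <- match.arg(shape)
  S <- matrix(0, 6, 6)
  if (shape == "sphere") {
    s_d <- (7 - 5 * nu) / (15 * (1 - nu))
    s_o <- (5 * nu - 1) / (15 * (1 - nu))
    s_s <- (4 - 5 * nu) / (15 * (1 - nu))
    S[1:3, 1:3] <- s_o
    diag(S)[1:3] <- s_d
    diag(S)[4:6] <- 2 * s_s
  } else {
    S[1, 1] <- S[2, 2] <- (5 - 4 * nu) / (8 * (1 - nu))
    S[1, 2] <- S[2, 1] <- (4 * nu - 1) / (8 * (1 - nu))
    S[1, 3] <- S[2, 3] <- nu / (2 * (1 - nu))
    # row 3 zero: the infinite cylinder constrains no axial eigenstrain
    S[6, 6] <- 2 * (3 - 4 * nu) / (8 * (1 - nu))
    S[4, 4] <- S[5, 5] <- 2 * 0.25
  }
  S
}

# Mori-Tanaka effective stiffness for one inclusion phase of volume
# fraction f with Eshelby tensor S (all Voigt engineering operators).
mori_tanaka <- function(C0, C1, f, S) {
  if (f <= 0) return(C0)
  I6 <- diag(6)
  Tdil <- solve(I6 + S %*% solve(C0, C1 - C0))
  Ceff <- C0 + f * (C1 - C0) %*% Tdil %*% solve((1 - f) * I6 + f * Tdil)
  (Ceff + t(Ceff)) / 2
}

# water inclusion: bulk modulus only (MPa), zero shear
water_stiffness <- function(K = 2200) {
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- K
  C
}
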