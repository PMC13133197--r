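#' Boundary flag for windowed tensor analysis
#'
#' Flags voxels whose analysis window extends too far outside the current
#' tissue label: when more than `max_outside_fraction` of the
#' `window^3` neighbourhood lies outside the label, the voxel is marked
#' isotropic and bypasses direction assignment, limiting boundary effects on
#' the estimated properties.
#'
#' @param label logical 3-D array (current tissue).
#' @param window odd window size in voxels (default 7).
#' @param max_outside_fraction flag threshold (default 0.25).
#' @return logical array, `TRUE` where flagged; voxels outside the label are
#'   `NA`.
#' @export
boundary_flag <- function(label, window = 7, max_outside_fraction = 0.25) {
  stopifnot(window %% 2 == 1, window >= 3)
  r <- (window - 1L) / 2L
  inside_count <- box_sum3(array(as.numeric(label), dim(label)), r)
  outside_frac <- 1 - inside_count / window^3
  flag <- outside_frac > max_outside_fraction
  flag[!label] <- NA
  flag
}

#' Morphologic degree of anisotropy
#'
#' `DA = 1 - lambda1 / lambda3` from the smallest and largest eigenvalues of
#' the normalized gradient structure tensor; 0 for isotropic texture,
#' approaching 1 for strongly oriented texture.
#'
#' @param lambda1,lambda3 smallest / largest GST eigenvalues (`lambda3 > 0`).
#' @return DA values in `[0, 1]` (`NA` where `lambda3` is zero).
#' @export
morphologic_anisotropy <- function(lambda1, lambda3) {
  da <- 1 - lambda1 / lambda3
  da[lambda3 <= 0] <- NA_real_
  pmin(pmax(da, 0), 1)
}

#' Kelvin-cell aspect ratio from GST eigenvalues
#'
#' `R = lambda3 / lambda1 >= 1`, the unit-cell height-to-width ratio
#' `H/D = tan(theta)`. Voxels with near-zero `lambda1` are capped at
#' `r_max` to avoid the `tan(theta) -> Inf` degeneracy.
#'
#' @param lambda1,lambda3 GST eigenvalues.
#' @param r_max cap for degenerate voxels (default 10).
#' @return list with `R` and `theta = atan(R)` (radians).
#' @export
aspect_ratio <- function(lambda1, lambda3, r_max = 10) {
  R <- ifelse(lambda1 > 0, lambda3 / lambda1, Inf)
  R[R > r_max] <- r_max
  R <- pmax(R, 1)
  list(R = R, theta = atan(R))
}

#' Per-voxel gradient structure tensor analysis
#'
#' Computes intensity gradients by central differences, averages the outer
#' products over a centred `window^3` neighbourhood restricted to the tissue
#' label, trace-normalizes the tensor, and eigen-decomposes it per voxel
#' (ascending eigenvalues `lambda1 <= lambda2 <= lambda3`). The eigenvector
#' of the smallest eigenvalue, `e1`, is the direction along which intensity
#' varies least -- along the trabeculae -- and is taken as the stiffest
#' material axis. Voxels flagged by [boundary_flag()] (window more than
#' `max_outside_fraction` outside the label) and voxels with zero tensor are
#' marked isotropic and carry no directions.
#'
#' @param vol an [image_volume] (isotropically resampled).
#' @param label logical array: the tissue to characterize.
#' @param window odd window size in voxels (default 7, i.e. about 1 mm
#'   radius at 0.326 mm spacing).
#' @param max_outside_fraction boundary-flag threshold (default 0.25).
#' @param sigma optional Gaussian pre-smoothing of the volume in mm
#'   (default 0: none).
#' @return object of class `fabric_field`: arrays `lambda1..lambda3`, `DA`,
#'   `R`, `isotropic` (logical), and `e1`, `e2`, `e3` as `n x 3` matrices for
#'   the labelled voxels plus `voxel_index` mapping rows to array positions.
#' @export
gradient_structure_tensor <- function(vol, label, window = 7,
                                      max_outside_fraction = 0.25,
                                      sigma = 0) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$values)
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  if (any(window > d)) stop("window larger than volume")
  x <- vol$values
  if (sigma > 0) x <- gauss_smooth3(x, sigma / vol$spacing)
  g <- gradient3(x, vol$spacing)
  lab <- array(as.numeric(label), d)
  r <- (window - 1L) / 2L
  # windowed sums of outer products over in-label voxels
  comps <- list(g[[1]] * g[[1]], g[[2]] * g[[2]], g[[3]] * g[[3]],
                g[[2]] * g[[3]], g[[1]] * g[[3]], g[[1]] * g[[2]])
  sums <- lapply(comps, function(c6) box_sum3(c6 * lab, r))
  cnt <- box_sum3(lab, r)
  flag <- boundary_flag(label, window, max_outside_fraction)

  idx <- which(label)
  n <- length(idx)
  M <- matrix(0, 6, n)
  for (k in 1:6) M[k, ] <- sums[[k]][idx] / pmax(cnt[idx], 1)
  tr <- M[1, ] + M[2, ] + M[3, ]
  zero <- tr <= max(tr, 0) * 1e-12 | tr == 0
  Mn <- M
  nz <- which(!zero)
  if (length(nz)) Mn[, nz] <- sweep(M[, nz, drop = FALSE], 2, tr[nz], "/")
  eig <- .eig_sym3_batch(Mn)
  lam <- pmax(eig$values, 0)  # GST is positive semidefinite
  iso_flag <- flag[idx] | zero
  lam[, zero] <- 0

  out_arr <- function(v) { a <- array(NA_real_, d); a[idx] <- v; a }
  da <- morphologic_anisotropy(lam[1, ], lam[3, ])
  da[iso_flag] <- NA_real_
  ar <- aspect_ratio(pmax(lam[1, ], .Machine$double.eps * (lam[3, ] > 0)),
                     lam[3, ])
  R <- ar$R
  R[iso_flag] <- NA_real_
  vec <- eig$vectors
  vec[, iso_flag] <- NA_real_
  structure(list(
    lambda1 = out_arr(lam[1, ]), lambda2 = out_arr(lam[2, ]),
    lambda3 = out_arr(lam[3, ]),
    DA = out_arr(da), R = out_arr(R),
    isotropic = { a <- array(NA, d); a[idx] <- iso_flag; a },
    e1 = t(vec[1:3, , drop = FALSE]),
    e2 = t(vec[4:6, , drop = FALSE]),
    e3 = t(vec[7:9, , drop = FALSE]),
    voxel_index = idx, dim = d,
    spacing = vol$spacing, origin = vol$origin, window = window),
    class = "fabric_field")
}

#' @export
print.fabric_field <- function(x, ...) {
  n <- length(x$voxel_index)
  iso <- x$isotropic[x$voxel_index]
  cat(sprintf("fabric_field: %d labelled voxels, %.1f%% flagged isotropic\n",
              n, 100 * mean(iso)))
  if (any(!iso))
    cat(sprintf("  DA median %.3f, R median %.2f (window %d)\n",
                median(x$DA[x$voxel_index][!iso]),
                median(x$R[x$voxel_index][!iso]), x$window))
  invisible(x)
}

# Separable Gaussian smoothing, sigma in voxels per axis.
gauss_smooth3 <- function(x, sigma_vox) {
  d <- dim(x)
  for (a in 1:3) {
    s <- sigma_vox[min(a, length(sigma_vox))]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- dnorm(seq(-r, r), sd = s)
    w <- w / sum(w)
    acc <- array(0, d)
    for (k in seq_along(w)) {
      off <- c(0L, 0L, 0L)
      off[a] <- k - r - 1L
      acc <- acc + w[k] * shift3_replicate(x, off, a)
    }
    x <- acc
  }
  x
}

# shift with edge replication along one axis
shift3_replicate <- function(x, off, axis) {
  d <- dim(x)
  idx <- lapply(1:3, function(a) seq_len(d[a]))
  i <- idx[[axis]] - off[axis]
  i <- pmin(pmax(i, 1L), d[axis])
  idx[[axis]] <- i
  out <- x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(out) <- d
  out
}

#' Summary statistics of a fabric field
#'
#' Per-voxel medians (DA, R) over unflagged voxels, and the degree of
#' anisotropy of the pooled tensor: the average of the trace-normalized
#' per-voxel structure tensors, whose DA estimates the anisotropy of the
#' underlying texture without the positive sampling bias of the per-voxel
#' estimates (the per-voxel DA of any finite-window estimate has a noise
#' floor; see the methods vignette).
#'
#' @param fabric a `fabric_field`.
#' @param reference_direction optional unit vector; when given, the angular
#'   error of the stiff axis `e1` against it is summarized.
#' @return list with `n`, `flagged_fraction`, `median_DA`, `median_R`,
#'   `pooled_DA`, `pooled_e1`, and (optionally) `median_angle_deg`.
#' @export
fabric_summary <- function(fabric, reference_direction = NULL) {
  stopifnot(inherits(fabric, "fabric_field"))
  idx <- fabric$voxel_index
  iso <- fabric$isotropic[idx]
  ok <- which(!iso)
  lam <- cbind(fabric$lambda1[idx][ok], fabric$lambda2[idx][ok],
               fabric$lambda3[idx][ok])
  evec <- list(fabric$e1[ok, , drop = FALSE], fabric$e2[ok, , drop = FALSE],
               fabric$e3[ok, , drop = FALSE])
  M <- matrix(0, 3, 3)
  for (k in 1:3) {
    e <- evec[[k]]
    l <- lam[, k]
    M <- M + matrix(c(sum(l * e[, 1]^2), sum(l * e[, 1] * e[, 2]),
                      sum(l * e[, 1] * e[, 3]),
                      sum(l * e[, 1] * e[, 2]), sum(l * e[, 2]^2),
                      sum(l * e[, 2] * e[, 3]),
                      sum(l * e[, 1] * e[, 3]), sum(l * e[, 2] * e[, 3]),
                      sum(l * e[, 3]^2)), 3, 3)
  }
  M <- M / length(ok)
  ev <- eigen(M, symmetric = TRUE)
  pooled_DA <- 1 - min(ev$values) / max(ev$values)
  out <- list(n = length(idx), flagged_fraction = mean(iso),
              median_DA = median(fabric$DA[idx][ok]),
              median_R = median(fabric$R[idx][ok]),
              pooled_DA = pooled_DA,
              pooled_e1 = ev$vectors[, which.min(ev$values)])
  if (!is.null(reference_direction)) {
    u <- reference_direction / sqrt(sum(reference_direction^2))
    cosang <- pmin(abs(evec[[1]] %*% u), 1)
    out$median_angle_deg <- median(acos(cosang)) * 180 / pi
  }
  out
}
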