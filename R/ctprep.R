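#' Calibration parameters for the HU-to-porosity laws
#'
#' Holds the anchors of the two split linear porosity laws. Trabecular bone:
#' porosity equals `phi_mode_trab` (default 0.85) at the trabecular HU mode
#' and `phi_max_trab` (default 0.92) at the trabecular HU minimum. Cortical
#' bone: porosity is zero at `hu_threshold` (the HU value at the chosen
#' cumulative frequency of the fitted HU distribution, default level 0.98,
#' above which voxels count as dense cortical bone) and `phi_max_cort`
#' (default 0.5) at the cortical HU minimum.
#'
#' @param hu_mode_trab HU mode inside the trabecular label.
#' @param hu_min_trab lowest HU inside the trabecular label.
#' @param hu_threshold HU at the fitted cumulative frequency `cdf_level`.
#' @param hu_min_cort lowest HU inside the cortical label.
#' @param phi_max_trab,phi_mode_trab,phi_max_cort porosity anchors.
#' @param cdf_level cumulative frequency defining `hu_threshold`.
#' @param distribution_family name of the fitted HU distribution family.
#' @return object of class `calibration_params`.
#' @export
calibration_params <- function(hu_mode_trab, hu_min_trab, hu_threshold,
                               hu_min_cort, phi_max_trab = 0.92,
                               phi_mode_trab = 0.85, phi_max_cort = 0.5,
                               cdf_level = 0.98,
                               distribution_family = "skewnormal") {
  stopifnot(is.numeric(hu_mode_trab), is.numeric(hu_min_trab),
            is.numeric(hu_threshold), is.numeric(hu_min_cort))
  if (!(hu_min_trab < hu_mode_trab))
    stop("hu_min_trab must be below hu_mode_trab")
  if (!(hu_min_cort < hu_threshold))
    stop("hu_min_cort must be below hu_threshold")
  if (!(phi_mode_trab > 0 && phi_mode_trab < phi_max_trab && phi_max_trab <= 1))
    stop("need 0 < phi_mode_trab < phi_max_trab <= 1")
  if (!(phi_max_cort > 0 && phi_max_cort < 1))
    stop("need 0 < phi_max_cort < 1")
  structure(list(hu_mode_trab = hu_mode_trab, hu_min_trab = hu_min_trab,
                 hu_threshold = hu_threshold, hu_min_cort = hu_min_cort,
                 phi_max_trab = phi_max_trab, phi_mode_trab = phi_mode_trab,
                 phi_max_cort = phi_max_cort, cdf_level = cdf_level,
                 distribution_family = distribution_family),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat("HU-to-porosity calibration\n")
  cat(sprintf("  trabecular: HU mode %.1f -> phi %.2f, HU min %.1f -> phi %.2f\n",
              x$hu_mode_trab, x$phi_mode_trab, x$hu_min_trab, x$phi_max_trab))
  cat(sprintf("  cortical:   HU threshold %.1f -> phi 0, HU min %.1f -> phi %.2f\n",
              x$hu_threshold, x$hu_min_cort, x$phi_max_cort))
  cat(sprintf("  threshold at cumulative frequency %.2f (%s fit)\n",
              x$cdf_level, x$distribution_family))
  invisible(x)
}

# ---- cubic B-spline resampling --------------------------------------------

# Recursive prefilter turning samples into cubic B-spline coefficients
# (mirror boundaries). Operates on the rows of a matrix.
bspline3_prefilter <- function(m) {
  z <- sqrt(3) - 2
  n <- nrow(m)
  if (n == 1) return(m * 1)
  lam <- 6
  m <- m * lam
  # causal initialisation on the mirror-extended signal, truncated horizon
  horizon <- ceiling(log(1e-14) / log(abs(z)))
  idx <- seq_len(horizon)
  p <- 2L * (n - 1L)
  fold <- ((idx - 1L) %% p)
  fold[fold > (n - 1L)] <- p - fold[fold > (n - 1L)]
  zk <- z ^ (idx - 1)
  cp <- matrix(0, n, ncol(m))
  cp[1, ] <- colSums(m[fold + 1L, , drop = FALSE] * zk)
  for (i in 2:n) cp[i, ] <- m[i, ] + z * cp[i - 1, ]
  cm <- matrix(0, n, ncol(m))
  cm[n, ] <- (z / (z * z - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (i in (n - 1):1) cm[i, ] <- z * (cm[i + 1, ] - cp[i, ])
  cm
}

# Sampling matrix evaluating a 1-D spline (degree 0, 1 or 3) defined on grid
# positions src (index space 0..n-1) at target index positions t.
bspline_sample_matrix <- function(n, t, degree) {
  if (degree == 0) {
    i <- pmin(pmax(round(t), 0), n - 1)
    return(Matrix::sparseMatrix(i = seq_along(t), j = i + 1, x = 1,
                                dims = c(length(t), n)))
  }
  mirror <- function(i) {
    # mirror-on-boundary index folding for 0..n-1
    if (n == 1) return(rep(0L, length(i)))
    p <- 2L * (n - 1L)
    i <- i %% p
    i[i < 0] <- i[i < 0] + p
    i[i > (n - 1L)] <- p - i[i > (n - 1L)]
    i
  }
  if (degree == 1) {
    i0 <- floor(t)
    f <- t - i0
    ii <- c(mirror(i0), mirror(i0 + 1)) + 1
    jj <- rep(seq_along(t), 2)
    xx <- c(1 - f, f)
  } else {
    i0 <- floor(t) - 1
    f <- t - (i0 + 1)
    w0 <- (1 - f)^3 / 6
    w1 <- (3 * f^3 - 6 * f^2 + 4) / 6
    w2 <- (-3 * f^3 + 3 * f^2 + 3 * f + 1) / 6
    w3 <- f^3 / 6
    ii <- c(mirror(i0), mirror(i0 + 1), mirror(i0 + 2), mirror(i0 + 3)) + 1
    jj <- rep(seq_along(t), 4)
    xx <- c(w0, w1, w2, w3)
  }
  Matrix::sparseMatrix(i = jj, j = ii, x = xx, dims = c(length(t), n))
}

apply_axis <- function(x, axis, fun) {
  d <- dim(x)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- fun(matrix(xp, nrow = dp[1]))
  dp[1] <- nrow(m)
  aperm(array(as.numeric(m), dp), order(perm))
}

#' Resample a volume to isotropic resolution
#'
#' Separable spline interpolation onto a cubic grid with the requested
#' spacing. Degree-3 interpolation uses the exact recursive B-spline
#' prefilter, so polynomials up to cubic order are reproduced to rounding
#' error. The output grid keeps the input origin and covers the same
#' physical extent (to within one voxel).
#'
#' @param vol an [image_volume].
#' @param target_mm positive scalar, output isotropic spacing in mm.
#' @param spline_degree 0 (nearest), 1 (linear) or 3 (cubic B-spline).
#' @return an [image_volume] with spacing `c(t, t, t)`.
#' @export
resample_isotropic <- function(vol, target_mm, spline_degree = 3) {
  stopifnot(inherits(vol, "image_volume"), target_mm > 0)
  if (!spline_degree %in% c(0, 1, 3)) stop("spline_degree must be 0, 1 or 3")
  if (any(!is.finite(vol$values))) stop("input volume has non-finite values")
  d <- dim(vol$values)
  extent <- d * vol$spacing
  nout <- pmax(2L, as.integer(round(extent / target_mm)))
  x <- vol$values
  if (spline_degree == 3) for (a in 1:3) x <- apply_axis(x, a, bspline3_prefilter)
  for (a in 1:3) {
    tpos <- ((seq_len(nout[a]) - 1) * target_mm) / vol$spacing[a]
    S <- bspline_sample_matrix(d[a], tpos, spline_degree)
    x <- apply_axis(x, a, function(m) as.matrix(S %*% m))
    d[a] <- nout[a]
  }
  image_volume(x, spacing = rep(target_mm, 3), origin = vol$origin)
}

# ---- threshold segmentation + 3-D morphology ------------------------------

erode3 <- function(mask, r) {
  s <- box_sum3(array(as.numeric(mask), dim(mask)), r)
  s >= ((2 * r + 1)^3 - 0.5)
}

dilate3 <- function(mask, r) {
  s <- box_sum3(array(as.numeric(mask), dim(mask)), r)
  s > 0.5
}

#' Threshold segmentation with optional binary morphology
#'
#' Voxels with `lo <= HU < hi` are labelled 1. Morphology operations (box
#' structuring element) are applied in order; closing is the standard tool to
#' restore continuity of a thin cortical shell whose HU dips below the
#' threshold where its thickness approaches the voxel size.
#'
#' @param vol an [image_volume].
#' @param lo,hi HU interval (use `-Inf` / `Inf` for open ends), `lo < hi`.
#' @param morphology_ops list of `c(op, radius)` entries with op one of
#'   `"close"`, `"open"`, `"dilate"`, `"erode"` and radius in voxels.
#' @return logical 3-D array.
#' @export
segment_by_threshold <- function(vol, lo, hi, morphology_ops = list()) {
  stopifnot(inherits(vol, "image_volume"))
  if (!(lo < hi)) stop("lo must be below hi")
  mask <- vol$values >= lo & vol$values < hi
  for (op in morphology_ops) {
    name <- as.character(op[[1]])
    r <- as.integer(op[[2]])
    mask <- switch(name,
                   close  = erode3(dilate3(mask, r), r),
                   open   = dilate3(erode3(mask, r), r),
                   dilate = dilate3(mask, r),
                   erode  = erode3(mask, r),
                   stop("unknown morphology op: ", name))
  }
  if (!any(mask)) warning("threshold segmentation produced an empty label")
  mask
}

# ---- HU histogram fit ------------------------------------------------------

# Skew-normal density/distribution/quantile (location xi, scale omega,
# slant alpha) for use with fitdistrplus.
dskn <- function(x, xi = 0, omega = 1, alpha = 0, log = FALSE) {
  if (omega <= 0) return(rep(if (log) -Inf else 0, length(x)))
  z <- (x - xi) / omega
  ld <- log(2) - log(omega) + dnorm(z, log = TRUE) +
    pnorm(alpha * z, log.p = TRUE)
  if (log) ld else exp(ld)
}

pskn <- function(q, xi = 0, omega = 1, alpha = 0) {
  vapply(q, function(qq) {
    stats::integrate(dskn, lower = xi - 12 * omega, upper = qq, xi = xi,
                     omega = omega, alpha = alpha, rel.tol = 1e-9,
                     stop.on.error = FALSE)$value
  }, numeric(1))
}

qskn <- function(p, xi = 0, omega = 1, alpha = 0) {
  vapply(p, function(pp) {
    stats::uniroot(function(q) pskn(q, xi, omega, alpha) - pp,
                   lower = xi - 12 * omega, upper = xi + 12 * omega,
                   extendInt = "upX", tol = 1e-8)$root
  }, numeric(1))
}

fit_one_family <- function(x, family) {
  if (family == "normal") {
    fit <- fitdistrplus::fitdist(x, "norm")
    list(logLik = as.numeric(logLik(fit)),
         q = function(p) qnorm(p, fit$estimate["mean"], fit$estimate["sd"]),
         estimate = fit$estimate)
  } else if (family == "gamma") {
    shift <- min(x) - 1e-6 * max(1, diff(range(x)))
    fit <- fitdistrplus::fitdist(x - shift, "gamma", lower = c(1e-8, 1e-8))
    list(logLik = as.numeric(logLik(fit)),
         q = function(p) shift + qgamma(p, fit$estimate["shape"],
                                        fit$estimate["rate"]),
         estimate = fit$estimate)
  } else if (family == "skewnormal") {
    start <- list(xi = mean(x) - sd(x) * 0.5, omega = sd(x), alpha = 1)
    fit <- fitdistrplus::fitdist(
      x, "skn", start = start,
      lower = c(-Inf, 1e-8, -50), upper = c(Inf, Inf, 50))
    est <- fit$estimate
    list(logLik = as.numeric(logLik(fit)),
         q = function(p) qskn(p, est["xi"], est["omega"], est["alpha"]),
         estimate = est)
  } else stop("unknown family: ", family)
}

#' Fit the HU histogram and extract the dense-bone threshold
#'
#' Fits a parametric distribution to HU samples by maximum likelihood and
#' returns its quantile at `cdf_level`. HU above this threshold are treated
#' as dense cortical bone with zero porosity. With `family = "auto"` the
#' skew-normal, normal and gamma fits compete on log-likelihood (bone HU
#' histograms are typically right-skewed, so the skew-normal usually wins).
#' If no fit converges the empirical quantile is returned, flagged.
#'
#' @param hu_samples numeric vector of HU values (>= 100 samples).
#' @param family `"auto"`, `"skewnormal"`, `"normal"`, `"gamma"`, or
#'   `"empirical"` for the plain sample quantile.
#' @param cdf_level cumulative frequency (default 0.98).
#' @return list with `threshold`, `family`, `logLik`, `fallback` flag and a
#'   QQ summary (`qq_rmse`, deciles fitted vs empirical).
#' @export
fit_hu_threshold <- function(hu_samples, family = "auto", cdf_level = 0.98) {
  hu_samples <- hu_samples[is.finite(hu_samples)]
  if (length(hu_samples) < 100) stop("need at least 100 HU samples")
  if (family == "empirical") {
    return(list(threshold = as.numeric(quantile(hu_samples, cdf_level,
                                                type = 7)),
                family = "empirical", logLik = NA_real_, fallback = TRUE,
                qq_rmse = 0))
  }
  fams <- if (family == "auto") c("skewnormal", "normal", "gamma") else family
  fits <- list()
  for (f in fams) {
    res <- tryCatch(suppressWarnings(fit_one_family(hu_samples, f)),
                    error = function(e) NULL)
    if (!is.null(res) && is.finite(res$logLik)) fits[[f]] <- res
  }
  if (length(fits) == 0) {
    thr <- as.numeric(quantile(hu_samples, cdf_level, type = 7))
    return(list(threshold = thr, family = "empirical", logLik = NA_real_,
                fallback = TRUE, qq_rmse = 0))
  }
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  best <- names(fits)[which.max(ll)]
  fit <- fits[[best]]
  probs <- seq(0.1, 0.9, by = 0.1)
  qq_fit <- fit$q(probs)
  qq_emp <- as.numeric(quantile(hu_samples, probs, type = 7))
  list(threshold = as.numeric(fit$q(cdf_level)), family = best,
       logLik = fit$logLik, fallback = FALSE, estimate = fit$estimate,
       qq_rmse = sqrt(mean((qq_fit - qq_emp)^2)),
       qq = data.frame(p = probs, fitted = qq_fit, empirical = qq_emp))
}

# ---- porosity laws ---------------------------------------------------------

#' HU to porosity, trabecular law
#'
#' Linear law anchored at the trabecular HU mode (porosity
#' `phi_mode_trab`) and the trabecular HU minimum (porosity `phi_max_trab`),
#' clamped to `[0, 1]`; the fraction of clamped voxels is attached as the
#' `"clamped_fraction"` attribute.
#'
#' @param hu numeric vector/array of HU values.
#' @param cal a [calibration_params] object.
#' @return porosity values with the same shape as `hu`.
#' @export
hu_to_porosity_trabecular <- function(hu, cal) {
  stopifnot(inherits(cal, "calibration_params"))
  phi <- cal$phi_mode_trab +
    (hu - cal$hu_mode_trab) * (cal$phi_max_trab - cal$phi_mode_trab) /
      (cal$hu_min_trab - cal$hu_mode_trab)
  clamped <- mean(phi < 0 | phi > 1)
  phi <- pmin(pmax(phi, 0), 1)
  if (is.array(hu)) dim(phi) <- dim(hu)
  attr(phi, "clamped_fraction") <- clamped
  phi
}

#' HU to porosity, cortical law
#'
#' Linear law: zero porosity at `hu_threshold` (and above: dense cortical
#' bone), `phi_max_cort` at the cortical HU minimum; clamped to
#' `[0, phi_max_cort]`.
#'
#' @inheritParams hu_to_porosity_trabecular
#' @return porosity values with the same shape as `hu`.
#' @export
hu_to_porosity_cortical <- function(hu, cal) {
  stopifnot(inherits(cal, "calibration_params"))
  phi <- (cal$hu_threshold - hu) / (cal$hu_threshold - cal$hu_min_cort) *
    cal$phi_max_cort
  clamped <- mean(phi < 0 | phi > cal$phi_max_cort)
  phi <- pmin(pmax(phi, 0), cal$phi_max_cort)
  if (is.array(hu)) dim(phi) <- dim(hu)
  attr(phi, "clamped_fraction") <- clamped
  phi
}

#' Build a per-voxel porosity field from labels and calibration
#'
#' Applies the trabecular law inside the trabecular label and the cortical
#' law inside the cortical label; voxels outside both labels carry no
#' porosity (NA) and tissue class 0.
#'
#' @param vol an [image_volume] of HU values.
#' @param cortical,trabecular logical arrays (same dims as `vol`).
#' @param cal a [calibration_params].
#' @return object of class `porosity_field`: list with `porosity` (array),
#'   `tissue` (integer array: 0 outside, 1 cortical, 2 trabecular), and the
#'   grid metadata.
#' @export
porosity_field <- function(vol, cortical, trabecular, cal) {
  stopifnot(inherits(vol, "image_volume"))
  if (any(cortical & trabecular)) stop("cortical and trabecular labels overlap")
  phi <- array(NA_real_, dim(vol$values))
  tissue <- array(0L, dim(vol$values))
  if (any(cortical)) {
    phi[cortical] <- hu_to_porosity_cortical(vol$values[cortical], cal)
    tissue[cortical] <- 1L
  }
  if (any(trabecular)) {
    phi[trabecular] <- hu_to_porosity_trabecular(vol$values[trabecular], cal)
    tissue[trabecular] <- 2L
  }
  structure(list(porosity = phi, tissue = tissue, spacing = vol$spacing,
                 origin = vol$origin, calibration = cal),
            class = "porosity_field")
}

#' @export
print.porosity_field <- function(x, ...) {
  n <- table(factor(x$tissue, levels = 0:2,
                    labels = c("outside", "cortical", "trabecular")))
  cat("porosity_field:", paste(names(n), n, collapse = ", "), "\n")
  inside <- x$tissue > 0
  if (any(inside))
    cat(sprintf("  porosity range [%.3f, %.3f]\n",
                min(x$porosity[inside]), max(x$porosity[inside])))
  invisible(x)
}
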