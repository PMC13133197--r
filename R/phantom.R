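#' Specification of a synthetic vertebra phantom
#'
#' Parameters of the synthetic CT phantom that stands in for a clinical
#' lumbar scan: an ellipse-cylinder vertebral body with a thin high-HU
#' cortical shell, a trabecular core whose HU histogram is unimodal with a
#' high-HU tail, and an oriented trabecular texture with controllable
#' principal direction and degree of anisotropy.
#'
#' The trabecular texture is an oriented rod pattern: soft Gaussian-profile
#' rods (radius `texture_scale`, spacing `rod_spacing_mm`) aligned with
#' `texture_direction`, mixed with band-limited isotropic noise whose
#' amplitude is calibrated, from the measured gradient moments of the two
#' components, so the expected (pooled) gradient-structure-tensor degree of
#' anisotropy equals `texture_anisotropy`. The weakest-gradient GST axis
#' then converges to `texture_direction`. At `texture_anisotropy` below
#' 0.03 the rods are dropped and the texture is isotropic noise alone.
#'
#' @param body_half_axes mm, half-axes (x, y, z) of the vertebral body.
#' @param cortical_thickness mm; scalar, or a function of world coordinates
#'   `(x, y, z)` returning the local shell thickness (may dip to one voxel).
#' @param spacing mm voxel spacing; default anisotropic 0.326 x 0.326 x 0.6,
#'   typical of clinical multidetector CT.
#' @param hu_cortical_range HU interval of the cortical shell.
#' @param hu_trabecular_mode HU mode of the trabecular core.
#' @param hu_trabecular_spread HU scale of the trabecular histogram.
#' @param texture_direction unit vector: principal trabecular direction.
#' @param texture_anisotropy target degree of anisotropy in `[0, 1)`.
#' @param texture_scale mm, Gaussian radius of the rod profiles.
#' @param rod_spacing_mm mm, mean transverse spacing of the rods.
#' @param rod_jitter_sd radian-scale jitter of individual rod directions.
#' @param noise_band_mm mm, correlation length of the isotropic noise
#'   component (band-limiting keeps it isotropic through resampling).
#' @param hu_skew skewness of the high-HU tail for the rod-free
#'   (isotropic-noise-only) texture; ignored when rods are present, whose
#'   profile itself forms the tail.
#' @param noise_sd HU, additive white measurement noise.
#' @param margin_mm padding of soft tissue around the body.
#' @param seed integer RNG seed: fixed seed gives bit-identical volumes.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_half_axes = c(18, 14, 12),
                         cortical_thickness = 0.6,
                         spacing = c(0.326, 0.326, 0.6),
                         hu_cortical_range = c(700, 1100),
                         hu_trabecular_mode = 200,
                         hu_trabecular_spread = 55,
                         texture_direction = c(0, 0, 1),
                         texture_anisotropy = 0.5,
                         texture_scale = 0.30,
                         rod_spacing_mm = 1.1,
                         rod_jitter_sd = 0.03,
                         noise_band_mm = 0.20,
                         hu_skew = 0.2,
                         noise_sd = 8,
                         margin_mm = 3,
                         seed = 1L) {
  if (length(body_half_axes) != 3 || any(!is.finite(body_half_axes)) ||
      any(body_half_axes <= 1))
    stop("degenerate body half-axes (need three finite values > 1 mm)")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (texture_anisotropy < 0 || texture_anisotropy >= 1)
    stop("texture_anisotropy must be in [0, 1)")
  if (hu_cortical_range[1] <= hu_trabecular_mode)
    stop("cortical HU range must lie above the trabecular mode")
  texture_direction <- texture_direction / sqrt(sum(texture_direction^2))
  structure(list(body_half_axes = body_half_axes,
                 cortical_thickness = cortical_thickness,
                 spacing = spacing, hu_cortical_range = hu_cortical_range,
                 hu_trabecular_mode = hu_trabecular_mode,
                 hu_trabecular_spread = hu_trabecular_spread,
                 texture_direction = texture_direction,
                 texture_anisotropy = texture_anisotropy,
                 texture_scale = texture_scale,
                 rod_spacing_mm = rod_spacing_mm,
                 rod_jitter_sd = rod_jitter_sd,
                 noise_band_mm = noise_band_mm, hu_skew = hu_skew,
                 noise_sd = noise_sd, margin_mm = margin_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  code
}

# Anisotropic Gaussian filtering of white noise via FFT. sigma_par/sigma_perp
# in mm, u a unit direction. Returns a standardized (zero-mean unit-sd) field.
oriented_noise <- function(d, spacing, u, sigma_perp, sigma_par) {
  noise <- array(rnorm(prod(d)), d)
  freqs <- lapply(1:3, function(a) {
    n <- d[a]
    k <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / (n * spacing[a])
    if (n == 1) k <- 0
    k
  })
  kx <- array(freqs[[1]], d)
  ky <- array(rep(freqs[[2]], each = d[1]), d)
  kz <- array(rep(freqs[[3]], each = d[1] * d[2]), d)
  kd <- kx * u[1] + ky * u[2] + kz * u[3]
  k2 <- kx^2 + ky^2 + kz^2
  H <- exp(-2 * pi^2 * (sigma_perp^2 * k2 + (sigma_par^2 - sigma_perp^2) * kd^2))
  f <- Re(fft(fft(noise) * H, inverse = TRUE)) / prod(d)
  (f - mean(f)) / sd(f)
}

# Monotone exponential skewing Y = (exp(sZ) - 1)/s of a standard normal
# field: produces the high-HU tail while keeping the histogram unimodal.
# The density mode sits at z = -s, i.e. y = (exp(-s^2) - 1)/s, and the
# standard deviation is sqrt(exp(s^2)(exp(s^2) - 1))/s; both are removed so
# the re-scaled variable has its mode at 0 and unit scale.
skew_transform <- function(z, s) {
  if (s == 0) return(z)
  y <- (exp(s * z) - 1) / s
  mode_y <- (exp(-s^2) - 1) / s
  sd_y <- sqrt(exp(s^2) * (exp(s^2) - 1)) / s
  (y - mode_y) / sd_y
}

density_mode <- function(x) {
  dd <- density(x, n = 512)
  dd$x[which.max(dd$y)]
}

# Oriented-rod trabecular texture with anisotropy-calibrated noise floor.
# Rods (Gaussian profile sigma = texture_scale) are aligned with
# texture_direction; band-limited isotropic noise is added with an
# amplitude solved from the measured gradient moments of both components so
# the expected GST anisotropy equals texture_anisotropy. Returns a
# standardized (unit-sd) field.
rod_texture <- function(d, spacing, spec) {
  u <- spec$texture_direction
  a <- spec$texture_anisotropy
  nf <- if (spec$noise_band_mm > 0)
    oriented_noise(d, spacing, c(0, 0, 1), spec$noise_band_mm,
                   spec$noise_band_mm)
  else array(rnorm(prod(d)), d)
  if (a < 0.03) return(skew_transform((nf - mean(nf)) / sd(nf), spec$hu_skew))
  box <- d * spacing
  # one rod per rod_spacing^2 of the largest box cross-section
  n_rod <- ceiling(prod(box) / min(box) / spec$rod_spacing_mm^2)
  p0 <- cbind(runif(n_rod, 0, box[1]), runif(n_rod, 0, box[2]),
              runif(n_rod, 0, box[3]))
  gj <- matrix(rnorm(3 * n_rod, sd = spec$rod_jitter_sd), n_rod, 3)
  v <- sweep(gj, 2, u, "+")
  v <- v / sqrt(rowSums(v^2))
  Ld <- sqrt(sum(box^2))
  segs <- rbind(t(p0 - Ld * v), t(p0 + Ld * v))
  xs <- (seq_len(d[1]) - 0.5) * spacing[1]
  ys <- (seq_len(d[2]) - 0.5) * spacing[2]
  zs <- (seq_len(d[3]) - 0.5) * spacing[3]
  pts <- rbind(rep(xs, times = d[2] * d[3]),
               rep(rep(ys, each = d[1]), times = d[3]),
               rep(zs, each = d[1] * d[2]))
  dist <- .min_dist_to_segments(pts, segs)
  rodf <- array(exp(-dist^2 / (2 * spec$texture_scale^2)), d)
  # calibrate the noise amplitude from gradient second moments
  gr <- gradient3(rodf, spacing)
  gpar <- gr[[1]] * u[1] + gr[[2]] * u[2] + gr[[3]] * u[3]
  g2 <- gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2
  lam_par <- mean(gpar^2)
  lam_perp <- (mean(g2) - lam_par) / 2
  gn <- gradient3(nf, spacing)
  lam_n <- mean(gn[[1]]^2 + gn[[2]]^2 + gn[[3]]^2) / 3
  nu <- ((1 - a) * lam_perp - lam_par) / a
  s <- if (nu > 0 && lam_n > 0) sqrt(nu / lam_n) else 0
  tex <- rodf + s * nf
  (tex - mean(tex)) / sd(tex)
}

# Signed superellipsoid form: <= 1 inside. Round in (x, y), flat-ish in z.
body_form <- function(X, Y, Z, half, zpow = 6) {
  (X / half[1])^2 + (Y / half[2])^2 + abs(Z / half[3])^zpow
}

phantom_grid <- function(spec, z_half_extent) {
  half <- spec$body_half_axes
  ext <- c(half[1] + spec$margin_mm, half[2] + spec$margin_mm,
           z_half_extent + spec$margin_mm)
  d <- as.integer(ceiling(2 * ext / spec$spacing)) + 1L
  origin <- -(d - 1) / 2 * spec$spacing
  list(d = d, origin = origin)
}

# Core generator: builds HU + labels for bodies centred at z = centres.
phantom_build <- function(spec, centres) {
  g <- phantom_grid(spec, max(abs(centres)) + spec$body_half_axes[3])
  d <- g$d
  xs <- g$origin[1] + (seq_len(d[1]) - 1) * spec$spacing[1]
  ys <- g$origin[2] + (seq_len(d[2]) - 1) * spec$spacing[2]
  zs <- g$origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3]
  X <- array(xs, d)
  Y <- array(rep(ys, each = d[1]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  half <- spec$body_half_axes
  tfun <- spec$cortical_thickness
  thick <- if (is.function(tfun)) tfun(X, Y, Z) else tfun

  tissue <- array(0L, d)   # 0 outside, 1 cortical, 2 trabecular
  body_id <- array(0L, d)
  for (b in seq_along(centres)) {
    Zb <- Z - centres[b]
    f_out <- body_form(X, Y, Zb, half)
    f_in <- body_form(X, Y, Zb, pmax(half - thick, 0.5))
    inside <- f_out <= 1
    core <- f_in <= 1
    tissue[inside & !core] <- 1L
    tissue[core] <- 2L
    body_id[inside] <- b
  }

  trab <- tissue == 2L
  cort <- tissue == 1L
  tex <- rod_texture(d, spec$spacing, spec)
  # centre the texture mode so the trabecular HU mode lands on target
  y <- tex - density_mode(tex[trab])
  hu <- array(40, d)                                # soft tissue baseline
  hu <- hu + 15 * oriented_noise(d, spec$spacing, c(0, 0, 1), 0.6, 0.6)
  hu[trab] <- spec$hu_trabecular_mode + spec$hu_trabecular_spread * y[trab]
  cr <- spec$hu_cortical_range
  cort_tex <- pmin(pmax(tex[cort] * 0.18 + 0.5, 0), 1)
  hu[cort] <- cr[1] + (cr[2] - cr[1]) * cort_tex
  if (spec$noise_sd > 0) hu <- hu + rnorm(prod(d), sd = spec$noise_sd)

  vol <- image_volume(hu, spacing = spec$spacing, origin = g$origin)

  # ground-truth porosity through the package's own calibration laws,
  # anchored to the generated histogram
  cal <- calibration_params(
    hu_mode_trab = spec$hu_trabecular_mode,
    hu_min_trab = min(hu[trab]),
    hu_threshold = as.numeric(quantile(hu[trab | cort], 0.98)),
    hu_min_cort = min(hu[cort]))
  phi <- array(NA_real_, d)
  phi[trab] <- hu_to_porosity_trabecular(hu[trab], cal)
  phi[cort] <- hu_to_porosity_cortical(hu[cort], cal)

  dir_truth <- matrix(NA_real_, sum(trab), 3)
  dir_truth[, 1] <- spec$texture_direction[1]
  dir_truth[, 2] <- spec$texture_direction[2]
  dir_truth[, 3] <- spec$texture_direction[3]

  truth <- structure(list(
    labels = tissue, body_id = body_id, porosity_truth = phi,
    direction_truth = dir_truth, direction_index = which(trab),
    calibration = cal, spec = spec), class = "phantom_truth")
  list(volume = vol, truth = truth)
}

#' Generate a synthetic vertebra phantom
#'
#' Builds a CT-like HU volume of a single vertebral body plus ground truth
#' (labels, per-voxel porosity through the calibration laws, trabecular
#' texture direction). Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec].
#' @return list with `volume` (an [image_volume]) and `truth` (labels,
#'   porosity truth, direction truth, calibration used).
#' @export
make_vertebra_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, phantom_build(spec, centres = 0))
}

#' Generate a two-vertebra scene with a disc-space gap
#'
#' Two stacked vertebral bodies separated by `gap_mm` of soft tissue (the
#' disc space a fusion cage fills). The returned `gap` element carries the
#' bounding planes and the elliptical endplate footprint for scaffold
#' fitting.
#'
#' @param spec a [phantom_spec].
#' @param gap_mm positive disc-space thickness in mm.
#' @return list with `volume`, `truth` (with `body_id` 1 = lower, 2 = upper)
#'   and `gap` (list: `z_lower`, `z_upper`, `footprint_half_axes`).
#' @export
make_two_vertebra_scene <- function(spec = phantom_spec(), gap_mm = 9) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!(gap_mm > 0)) stop("gap_mm must be positive: bodies would overlap")
  az <- spec$body_half_axes[3]
  centres <- c(-(az + gap_mm / 2), az + gap_mm / 2)
  out <- with_seed(spec$seed, phantom_build(spec, centres = centres))
  out$gap <- list(z_lower = -gap_mm / 2, z_upper = gap_mm / 2,
                  footprint_half_axes = spec$body_half_axes[1:2],
                  centres = centres)
  out
}

#' Dump phantom generation parameters to YAML
#'
#' Writes all generator parameters to a YAML file for provenance.
#'
#' @param spec a [phantom_spec].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phantom_config <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  lst <- unclass(spec)
  lst$cortical_thickness <- if (is.function(lst$cortical_thickness))
    "<function>" else lst$cortical_thickness
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: body %g x %g x %g mm, spacing %g x %g x %g mm\n",
    x$body_half_axes[1], x$body_half_axes[2], x$body_half_axes[3],
    x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf(
    "  trabecular HU mode %g (spread %g), cortical HU [%g, %g]\n",
    x$hu_trabecular_mode, x$hu_trabecular_spread,
    x$hu_cortical_range[1], x$hu_cortical_range[2]))
  cat(sprintf("  texture DA %g along (%.2f, %.2f, %.2f), seed %d\n",
              x$texture_anisotropy, x$texture_direction[1],
              x$texture_direction[2], x$texture_direction[3], x$seed))
  invisible(x)
}
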