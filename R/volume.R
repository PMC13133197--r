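#' 3-D scalar image volume
#'
#' Container for a CT-like scalar grid with voxel spacing and world origin.
#' World coordinates follow the convention `world = origin + index * spacing`
#' with 0-based indices (the first voxel centre sits at `origin`); R arrays
#' are addressed 1-based, so voxel `[i, j, k]` is at
#' `origin + (c(i, j, k) - 1) * spacing`. Axis order is (x, y, z), x fastest.
#'
#' @param values numeric 3-D array (Hounsfield units for CT volumes).
#' @param spacing positive numeric length-3, voxel spacing in mm.
#' @param origin numeric length-3, world position of the first voxel centre (mm).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("image_volume: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Voxel-centre world coordinates along each axis
#'
#' @param vol an [image_volume].
#' @return list of three numeric vectors (x, y, z coordinates in mm).
#' @export
voxel_coords <- function(vol) {
  d <- dim(vol$values)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving the spacing/origin metadata used
#' throughout the package.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol an [image_volume] (for writing).
#' @return `read_volume` returns an [image_volume]; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  hdr <- RNifti::niftiHeader(img)
  org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  image_volume(arr, spacing = sp, origin = org)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  affine <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- internal array helpers -------------------------------------------------

# Separable box-sum filter: at each voxel the sum of `x` over a centred
# (2r+1)^3 window, with zero padding outside. Vectorized via cumsum.
box_sum3 <- function(x, r) {
  if (r == 0) return(x)
  d <- dim(x)
  for (axis in 1:3) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- matrix(xp, nrow = dp[1])
    cs <- rbind(0, apply(m, 2, cumsum))
    n <- dp[1]
    hi <- pmin(seq_len(n) + r, n)
    lo <- pmax(seq_len(n) - r - 1, 0)
    m2 <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
    xp <- array(m2, dp)
    x <- aperm(xp, order(perm))
  }
  x
}

# Shift an array by integer offset (zero fill).
shift3 <- function(x, off) {
  d <- dim(x)
  idx <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) - off[a]
    i[i < 1 | i > d[a]] <- NA
    i
  })
  out <- x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out[is.na(out)] <- 0
  dim(out) <- d
  out
}

# Central-difference gradient of a 3-D array with one-sided differences at
# the faces; spacing-aware.
gradient3 <- function(x, spacing) {
  d <- dim(x)
  g <- vector("list", 3)
  for (a in 1:3) {
    ip <- im <- seq_len(d[a])
    ip <- pmin(ip + 1L, d[a]); im <- pmax(im - 1L, 1L)
    xp <- switch(a,
                 x[ip, , , drop = FALSE],
                 x[, ip, , drop = FALSE],
                 x[, , ip, drop = FALSE])
    xm <- switch(a,
                 x[im, , , drop = FALSE],
                 x[, im, , drop = FALSE],
                 x[, , im, drop = FALSE])
    den3 <- switch(a,
                   array(rep((ip - im) * spacing[a], times = d[2] * d[3]), d),
                   array(rep(rep((ip - im) * spacing[a], each = d[1]), d[3]), d),
                   array(rep((ip - im) * spacing[a], each = d[1] * d[2]), d))
    g[[a]] <- (xp - xm) / den3
  }
  g
}
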