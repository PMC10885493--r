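# Preprocessing: resampling to a uniform voxel grid, gray-level
# discretization, and Gaussian / Laplacian-of-Gaussian filtering.

#' Transform tags
#'
#' Texture features are computed on the raw image (`"N"`), a Gaussian-smoothed
#' image (`"G"`), or a Laplacian-of-Gaussian filtered image (`"LOG"`). A
#' transform tag records which, together with the filter scale in millimetres.
#'
#' @param kind one of `"N"`, `"G"`, `"LOG"`.
#' @param sigma_mm filter scale in mm; required (> 0) for `"G"` and `"LOG"`.
#' @return A `transform_tag` list.
#' @export
transform_tag <- function(kind = c("N", "G", "LOG"), sigma_mm = NULL) {
  kind <- match.arg(kind)
  if (kind != "N") {
    if (is.null(sigma_mm) || !is.finite(sigma_mm) || sigma_mm <= 0)
      stop("filtered transforms need sigma_mm > 0")
  } else sigma_mm <- NA_real_
  structure(list(kind = kind, sigma_mm = as.numeric(sigma_mm)),
            class = "transform_tag")
}

apply_transform <- function(volume, tag) {
  switch(tag$kind,
         N = volume,
         G = gaussian_filter(volume, tag$sigma_mm),
         LOG = log_filter(volume, tag$sigma_mm))
}

# --- axis-wise convolution with symmetric (mirror) boundary handling -------

slice_axis <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

conv_axis <- function(a, kernel, axis) {
  n <- dim(a)[axis]
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(a * kernel)
  # mirror padding (edge voxel repeated): ... 2 1 | 1 2 ... n | n n-1 ...
  left <- rev(seq_len(min(r, n)))
  right <- rev(seq_len(n))[seq_len(min(r, n))]
  if (r > n) { # degenerate tiny axis: clamp
    left <- rep(left, length.out = r)
    right <- rep(right, length.out = r)
  }
  ext_idx <- c(left, seq_len(n), right)
  ext <- slice_axis(a, axis, ext_idx)
  out <- array(0, dim(a))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * slice_axis(ext, axis, seq_len(n) + (j - 1L))
  }
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with the scale given in millimetres and
#' converted per axis through the voxel spacing, so the physical smoothing
#' scale is isotropic on anisotropic grids. Boundaries are mirror-padded.
#'
#' @param volume an [image_volume()].
#' @param sigma_mm Gaussian scale in millimetres (> 0).
#' @return A smoothed [image_volume()] on the same grid.
#' @export
gaussian_filter <- function(volume, sigma_mm) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.finite(sigma_mm) || sigma_mm <= 0) stop("sigma_mm must be > 0")
  out <- volume$values
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm / volume$spacing_mm[axis])
    out <- conv_axis(out, k, axis)
  }
  image_volume(out, volume$spacing_mm, volume$origin_mm)
}

#' Laplacian-of-Gaussian filter
#'
#' Smooths the volume with a Gaussian of scale `sigma_mm`, then applies the
#' 3D Laplacian (sum of second finite differences, scaled by the squared
#' voxel spacing so the result is per mm^2). A constant image maps to zero
#' and an affine ramp maps to ~0 away from boundaries.
#'
#' @inheritParams gaussian_filter
#' @return A filtered [image_volume()] on the same grid.
#' @export
log_filter <- function(volume, sigma_mm) {
  sm <- gaussian_filter(volume, sigma_mm)
  out <- array(0, dim(sm$values))
  for (axis in 1:3) {
    d2 <- conv_axis(sm$values, c(1, -2, 1), axis) / sm$spacing_mm[axis]^2
    out <- out + d2
  }
  image_volume(out, volume$spacing_mm, volume$origin_mm)
}

# --- resampling ------------------------------------------------------------

#' Resample an image/mask pair to a uniform voxel grid
#'
#' Resamples to the target spacing (default 1 x 1 x 3 mm, the grid used for
#' feature extraction) with trilinear interpolation for the image and
#' nearest-neighbour interpolation for the mask. The physical extent of the
#' grid is preserved to within one voxel and the origin is unchanged.
#'
#' @param volume an [image_volume()].
#' @param mask an aligned [voi_mask()].
#' @param target_spacing numeric length-3 target voxel size in mm.
#' @return A list with elements `volume` and `mask` on the new grid.
#' @export
resample <- function(volume, mask, target_spacing = c(1, 1, 3)) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "voi_mask"))
  check_aligned(volume, mask)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target_spacing must be 3 positive numbers")
  d_old <- dim(volume$values)
  sp_old <- volume$spacing_mm
  if (isTRUE(all.equal(sp_old, target_spacing, tolerance = 1e-8)))
    return(list(volume = volume, mask = mask))
  d_new <- pmax(1L, as.integer(round(d_old * sp_old / target_spacing)))

  # continuous source index (0-based) of each target voxel centre
  src <- lapply(1:3, function(k)
    (seq_len(d_new[k]) - 1) * target_spacing[k] / sp_old[k])
  g <- expand.grid(x = src[[1]], y = src[[2]], z = src[[3]],
                   KEEP.OUT.ATTRS = FALSE)

  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  x <- clamp(g$x, d_old[1] - 1); y <- clamp(g$y, d_old[2] - 1)
  z <- clamp(g$z, d_old[3] - 1)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  x1 <- pmin(x0 + 1, d_old[1] - 1); y1 <- pmin(y0 + 1, d_old[2] - 1)
  z1 <- pmin(z0 + 1, d_old[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) volume$values[1 + i + d_old[1] * (j + d_old[2] * k)]
  vals <-
    at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
    at(x1, y1, z0) * fx       * fy       * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y0, z1) * fx       * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy       * fz +
    at(x1, y1, z1) * fx       * fy       * fz
  new_vol <- image_volume(array(vals, d_new), target_spacing,
                          volume$origin_mm)

  xn <- clamp(round(x), d_old[1] - 1); yn <- clamp(round(y), d_old[2] - 1)
  zn <- clamp(round(z), d_old[3] - 1)
  mvals <- mask$values[1 + xn + d_old[1] * (yn + d_old[2] * zn)]
  if (sum(mvals) == 0) stop("mask is empty after resampling")
  new_mask <- voi_mask(array(mvals, d_new), target_spacing, mask$origin_mm)
  list(volume = new_vol, mask = new_mask)
}

# --- discretization --------------------------------------------------------

#' Discretize in-mask intensities to a fixed number of gray levels
#'
#' Fixed-bin-count discretization over the in-mask intensity range:
#' `level = 1 + floor(n_bins * (x - min) / (max - min + eps))`, clipped to
#' `n_bins`. A constant region maps entirely to level 1. Fixed bin counts
#' make downstream texture features invariant to affine rescaling of the
#' in-mask intensities.
#'
#' @param volume an [image_volume()].
#' @param mask an aligned, non-empty [voi_mask()].
#' @param n_bins number of gray levels (>= 2), default 32.
#' @return A `discretized_voi`: list with `levels` (integer array, 0 outside
#'   the mask, 1..n_bins inside), `n_levels`, and a `binning` record.
#' @export
discretize <- function(volume, mask, n_bins = 32L) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "voi_mask"))
  check_aligned(volume, mask)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  inm <- mask$values == 1L
  if (!any(inm)) stop("mask is empty")
  x <- volume$values[inm]
  rng <- range(x)
  lev <- array(0L, dim(volume$values))
  if (rng[2] > rng[1]) {
    eps <- (rng[2] - rng[1]) * 1e-9
    l <- 1L + as.integer(floor(n_bins * (x - rng[1]) / (rng[2] - rng[1] + eps)))
    lev[inm] <- pmin(l, n_bins)
  } else {
    lev[inm] <- 1L
  }
  structure(list(levels = lev, n_levels = n_bins,
                 binning = list(method = "fixed_bin_count", n_bins = n_bins,
                                range = rng)),
            class = "discretized_voi")
}
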