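# Morphologic features: computed from the mask geometry only.

#' Tumor volume in mm^3
#'
#' Sum of all voxels in the segmented VOI times the voxel volume.
#'
#' @param mask a non-empty [voi_mask()].
#' @return Volume in mm^3.
#' @export
morph_volume <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  n <- n_voxels_in_mask(mask)
  if (n == 0L) stop("mask is empty")
  n * prod(mask$spacing_mm)
}

mask_phys_coords <- function(mask) {
  idx <- which(mask$values == 1L) - 1L
  gs <- dim(mask$values)
  x <- idx %% gs[1]
  y <- (idx %/% gs[1]) %% gs[2]
  z <- idx %/% (gs[1] * gs[2])
  cbind(mask$origin_mm[1] + x * mask$spacing_mm[1],
        mask$origin_mm[2] + y * mask$spacing_mm[2],
        mask$origin_mm[3] + z * mask$spacing_mm[3])
}

#' Flatness of the tumor mask
#'
#' `sqrt(lambda_least / lambda_major)` of the eigenvalues of the covariance
#' of in-mask physical voxel coordinates (principal-axis least-to-major
#' length ratio), bounded in (0, 1]; 1 for a sphere, small for a pancake.
#'
#' @param mask a [voi_mask()] with at least 4 non-coplanar voxels.
#' @return Flatness in (0, 1].
#' @export
morph_flatness <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  co <- mask_phys_coords(mask)
  if (nrow(co) < 4L) stop("flatness needs at least 4 voxels")
  ev <- eigen(stats::cov(co), symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] <= 1e-10 * ev[1])
    stop("degenerate (coplanar) mask: flatness undefined")
  sqrt(ev[3] / ev[1])
}

morph_features <- function(mask) {
  c(volume = morph_volume(mask), flatness = morph_flatness(mask))
}
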