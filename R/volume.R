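#' 3D image volume with physical geometry
#'
#' An `image_volume` bundles a 3D numeric array of voxel values (Hounsfield
#' units for CT) with its voxel spacing and physical origin, following the
#' convention that the physical position of voxel (i, j, k) (0-based) is
#' `origin + c(i, j, k) * spacing`.
#'
#' @param values numeric 3D array of voxel intensities; must be finite.
#' @param spacing_mm numeric length-3 vector of strictly positive per-axis
#'   voxel sizes in millimetres.
#' @param origin_mm numeric length-3 physical offset in millimetres.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive numbers")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite numbers")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "image_volume")
}

#' Binary volume-of-interest mask
#'
#' A `voi_mask` is a binary (0/1) 3D grid aligned voxel-for-voxel with an
#' [image_volume()]: same array shape, spacing and origin.
#'
#' @param values 3D array containing only 0 and 1 (logical accepted).
#' @param spacing_mm,origin_mm geometry, as for [image_volume()].
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (is.logical(values)) values <- array(as.integer(values), dim(values))
  if (!all(values %in% c(0, 1)))
    stop("mask values must be binary (0/1)")
  v <- image_volume(values, spacing_mm, origin_mm)
  structure(list(values = array(as.integer(values), dim(values)),
                 spacing_mm = v$spacing_mm, origin_mm = v$origin_mm),
            class = "voi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing_mm, 4), collapse = " x "),
      "mm\n  value range [", signif(min(x$values), 5), ",",
      signif(max(x$values), 5), "]\n")
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("voi_mask:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing_mm, 4), collapse = " x "),
      "mm,", sum(x$values), "in-mask voxels\n")
  invisible(x)
}

n_voxels_in_mask <- function(mask) sum(mask$values)

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$values)))
    stop("image and mask grids have different shapes")
  if (!isTRUE(all.equal(volume$spacing_mm, mask$spacing_mm, tolerance = 1e-8)))
    stop("image and mask voxel spacings differ")
  if (!isTRUE(all.equal(volume$origin_mm, mask$origin_mm, tolerance = 1e-6)))
    stop("image and mask origins differ")
  invisible(TRUE)
}

#' Read / write volumes as NIfTI
#'
#' `write_volume()` stores an [image_volume()] or [voi_mask()] as a NIfTI-1
#' file carrying the voxel spacing and origin; `read_volume()` reads one back.
#' Reading with `as_mask = TRUE` validates that the grid is binary and returns
#' a [voi_mask()].
#'
#' @param x an `image_volume` or `voi_mask`.
#' @param path file path (conventionally `.nii` or `.nii.gz`).
#' @param as_mask logical; interpret the file as a binary mask.
#' @return `read_volume()` returns an `image_volume` or `voi_mask`.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "voi_mask"))
  img <- RNifti::asNifti(x$values)
  RNifti::pixdim(img) <- x$spacing_mm
  # origin goes through the qform translation column
  xf <- diag(c(x$spacing_mm, 1))
  xf[1:3, 4] <- x$origin_mm
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  if (as_mask) voi_mask(vals, spacing, origin)
  else image_volume(vals, spacing, origin)
}
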