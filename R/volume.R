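#' In-memory 3D image volume
#'
#' Container for a scalar 3D image on a regular grid, the unit the feature
#' pipeline consumes. Intensities are on a Hounsfield-unit-like scale.
#'
#' @param voxels 3D numeric array.
#' @param spacing_mm voxel spacing along each axis, mm (3 positive reals).
#' @param origin_mm world position of voxel (1,1,1), mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  voxels <- unclass(voxels)
  attributes(voxels) <- list(dim = dim(voxels))
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    stop("voxels must be a non-empty 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive reals")
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "image_volume")
}

#' Binary region-of-interest mask on the grid of a reference volume
#'
#' Mask values must be 0/1 (within 1e-3 of an integer in \{0, 1\}); anything
#' else is a validation error. When a reference image is supplied the mask
#' grid must match it: identical array dimensions and spacing/origin within
#' 1e-3 mm.
#'
#' @param voxels 3D array of 0/1 values.
#' @param spacing_mm,origin_mm grid metadata, as in [image_volume()].
#' @param reference optional `image_volume` to validate geometry against.
#' @return An object of class `roi_mask` (voxels stored as logical).
#' @export
roi_mask <- function(voxels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0),
                     reference = NULL) {
  voxels <- unclass(voxels)
  attributes(voxels) <- list(dim = dim(voxels))
  if (length(dim(voxels)) != 3L) stop("mask voxels must be a 3D array")
  v <- as.numeric(voxels)
  r <- round(v)
  if (any(!r %in% c(0, 1)) || any(abs(v - r) > 1e-3))
    stop("mask is not binary: values other than {0,1} found")
  m <- structure(list(voxels = array(r == 1, dim(voxels)),
                      spacing_mm = as.numeric(spacing_mm),
                      origin_mm = as.numeric(origin_mm)),
                 class = "roi_mask")
  if (!is.null(reference)) validate_geometry(m, reference)
  m
}

# Geometry agreement between a mask and its reference image: identical
# dims, spacing and origin within 1e-3 mm.
validate_geometry <- function(mask, image, tol = 1e-3) {
  if (!identical(dim(mask$voxels), dim(image$voxels)))
    stop("geometry error: mask grid ", paste(dim(mask$voxels), collapse = "x"),
         " does not match image grid ", paste(dim(image$voxels), collapse = "x"))
  if (any(abs(mask$spacing_mm - image$spacing_mm) > tol) ||
      any(abs(mask$origin_mm - image$origin_mm) > tol))
    stop("geometry error: mask spacing/origin differs from image beyond ",
         tol, " mm")
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  image_volume(array(as.numeric(img), dim(img)[1:3]),
               spacing_mm = RNifti::pixdim(img)[1:3],
               origin_mm = xf[1:3, 4])
}

#' Read a NIfTI mask and validate it against a reference image
#'
#' @param path path to a NIfTI-1 mask file valued \{0,1\}.
#' @param reference the [image_volume()] the mask belongs to.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, reference) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  roi_mask(array(as.numeric(img), dim(img)[1:3]),
           spacing_mm = RNifti::pixdim(img)[1:3],
           origin_mm = xf[1:3, 4],
           reference = reference)
}

#' Write a volume or mask as NIfTI-1
#'
#' @param x an `image_volume` or `roi_mask`.
#' @param path output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "roi_mask")) array(as.integer(x$voxels), dim(x$voxels))
         else x$voxels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing_mm, 4), collapse = " x "),
      "mm\n")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("roi_mask:", paste(dim(x$voxels), collapse = " x "),
      "grid,", sum(x$voxels), "foreground voxels\n")
  invisible(x)
}
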