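# Resampling and VOI preparation.
#
# Volumes are resampled onto an isotropic grid before feature extraction so
# that texture offsets and surface estimates are geometrically meaningful.
# Images use trilinear interpolation; masks nearest-neighbour (equivalently,
# linear interpolation thresholded at 0.5 for a binary mask).

# Map target grid (0-based index j, spacing s_new) into source fractional
# indices j * s_new / s_old, clamped to the source extent.
resample_array <- function(arr, spacing_old, spacing_new,
                           method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  if (all(abs(spacing_old - spacing_new) < 1e-9)) return(arr)
  dn <- pmax(1L, as.integer(round(d * spacing_old / spacing_new)))
  src <- lapply(1:3, function(a) {
    s <- (seq_len(dn[a]) - 1) * spacing_new[a] / spacing_old[a]
    pmin(pmax(s, 0), d[a] - 1)
  })
  if (method == "nearest") {
    idx <- lapply(1:3, function(a) as.integer(round(src[[a]])) + 1L)
    return(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  i0 <- lapply(1:3, function(a) as.integer(pmin(floor(src[[a]]), max(d[a] - 2, 0))))
  w <- lapply(1:3, function(a) src[[a]] - i0[[a]])
  out <- array(0, dn)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- pmin(i0[[1]] + cx, d[1] - 1L) + 1L
    iy <- pmin(i0[[2]] + cy, d[2] - 1L) + 1L
    iz <- pmin(i0[[3]] + cz, d[3] - 1L) + 1L
    wx <- if (cx == 1) w[[1]] else 1 - w[[1]]
    wy <- if (cy == 1) w[[2]] else 1 - w[[2]]
    wz <- if (cz == 1) w[[3]] else 1 - w[[3]]
    wt <- outer(outer(wx, wy), wz)
    out <- out + wt * arr[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Discretize intensities to integer grey levels
#'
#' Fixed-bin-count rule: `level = min(G, floor(G * (x - min) / (max - min)) + 1)`.
#' A constant input (max == min) maps every voxel to level 1. The fixed
#' bin-width rule is `level = floor((x - min) / width) + 1`.
#'
#' @param x numeric vector of intensities.
#' @param n_levels number of grey levels G (fixed bin count), or `NULL`.
#' @param bin_width fixed bin width, or `NULL`. Exactly one of `n_levels` /
#'   `bin_width` must be given.
#' @return integer vector of levels and the level count, as
#'   `list(levels, n_levels)`.
#' @export
discretize_intensities <- function(x, n_levels = NULL, bin_width = NULL) {
  if (is.null(n_levels) == is.null(bin_width))
    stop("give exactly one of n_levels or bin_width")
  lo <- min(x); hi <- max(x)
  if (!is.null(n_levels)) {
    g <- as.integer(n_levels)
    if (g < 1) stop("n_levels must be >= 1")
    if (hi == lo) return(list(levels = rep(1L, length(x)), n_levels = g))
    lev <- pmin(g, floor(g * (x - lo) / (hi - lo)) + 1)
    return(list(levels = as.integer(lev), n_levels = g))
  }
  if (bin_width <= 0) stop("bin_width must be positive")
  lev <- as.integer(floor((x - lo) / bin_width) + 1)
  list(levels = lev, n_levels = max(lev))
}

#' Build the analysis-ready volume of interest
#'
#' Resamples image and mask to an isotropic grid, optionally drops
#' foreground voxels outside an intensity range (an automatable surrogate
#' for manual exclusion of necrosis, calcification and gas), crops to the
#' mask bounding box, and discretizes intensities to integer grey levels.
#'
#' @param image an [image_volume()].
#' @param mask an [roi_mask()] on the same grid; must be nonempty.
#' @param iso_spacing_mm target isotropic spacing in mm, or `NULL` to keep
#'   the native grid. Default 1 mm.
#' @param n_levels,bin_width discretization rule; see
#'   [discretize_intensities()]. Default fixed bin count of 32.
#' @param resegment_range optional `(lo, hi)`: foreground voxels with
#'   intensity outside the open interval are dropped.
#' @return An object of class `voi`: raw foreground intensities, the
#'   discretized level array (0 outside the VOI), the cropped mask, grid
#'   spacing, and the level count.
#' @export
make_voi <- function(image, mask, iso_spacing_mm = 1, n_levels = 32,
                     bin_width = NULL, resegment_range = NULL) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  validate_geometry(mask, image)
  if (!any(mask$voxels)) stop("empty-VOI error: mask has no foreground voxels")
  sp <- image$spacing_mm
  img <- image$voxels
  msk <- mask$voxels
  if (!is.null(iso_spacing_mm)) {
    tgt <- rep(iso_spacing_mm, 3)
    if (any(abs(sp - tgt) > 1e-9)) {
      img <- resample_array(img, sp, tgt, "trilinear")
      msk <- resample_array(array(as.numeric(msk), dim(msk)), sp, tgt,
                            "nearest") >= 0.5
      sp <- tgt
    }
  }
  if (!any(msk)) stop("empty-VOI error: mask empty after resampling")
  if (!is.null(resegment_range)) {
    keep <- msk & img > resegment_range[1] & img < resegment_range[2]
    if (!any(keep)) stop("empty-VOI error: resegmentation removed all voxels")
    msk <- keep
  }
  # crop to bounding box
  idx <- which(msk, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  img <- img[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
             drop = FALSE]
  msk <- msk[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
             drop = FALSE]
  values <- img[msk]
  disc <- discretize_intensities(values, n_levels = n_levels,
                                 bin_width = bin_width)
  levels <- array(0L, dim(msk))
  levels[msk] <- disc$levels
  structure(list(values = values, levels = levels, mask = msk,
                 spacing_mm = sp, n_levels = disc$n_levels,
                 voxel_count = sum(msk), bbox_offset = rng[1, ] - 1L),
            class = "voi")
}

# Re-discretize an existing VOI at a different grey-level count without
# re-resampling (used to compute the catalogue's two discretizations).
rediscretize <- function(voi, n_levels) {
  disc <- discretize_intensities(voi$values, n_levels = n_levels)
  levels <- array(0L, dim(voi$mask))
  levels[voi$mask] <- disc$levels
  voi$levels <- levels
  voi$n_levels <- disc$n_levels
  voi
}

#' @export
print.voi <- function(x, ...) {
  cat("voi:", x$voxel_count, "voxels,", x$n_levels, "grey levels, grid",
      paste(dim(x$mask), collapse = " x "), "at",
      paste(signif(x$spacing_mm, 4), collapse = " x "), "mm\n")
  invisible(x)
}
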