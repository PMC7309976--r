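# Morphological (shape) features of a binary mask.

# Shift a logical 3D array by one voxel along an axis, padding with FALSE.
shift_mask <- function(m, axis, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (by == 1) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  if (d[axis] < 2) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

# Voxels of m with at least one background 6-neighbour (grid border counts
# as background).
boundary_voxels <- function(m) {
  interior <- m
  for (a in 1:3) for (b in c(-1, 1)) interior <- interior & shift_mask(m, a, b)
  m & !interior
}

# Mesh surface area by marching tetrahedra over a lightly anti-aliased
# (Gaussian-smoothed) copy of the mask, which removes the voxel staircase
# so smooth solids are measured to within a few percent. Masks too small
# to survive smoothing fall back to the binary midpoint mesh.
mesh_surface_area <- function(m, sp, sigma_vox = 0.7) {
  d <- dim(m)
  pad <- 3L
  dp <- d + 2L * pad
  arr <- array(0, dp)
  arr[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(m)
  field <- gauss_smooth3(arr, rep(sigma_vox, 3))
  if (max(field) <= 0.55) field <- arr  # tiny mask: binary fallback
  cpp_mesh_area(field, dp[1], dp[2], dp[3], sp[1], sp[2], sp[3], 0.5)
}

# Marching-squares perimeter of a 2D binary slice (lengths in mm).
slice_perimeter <- function(sl, sx, sy) {
  d <- dim(sl)
  p <- matrix(FALSE, d[1] + 2, d[2] + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1)] <- sl
  nx <- nrow(p); ny <- ncol(p)
  a <- p[-nx, -ny]; b <- p[-1, -ny]; cc <- p[-nx, -1]; dd <- p[-1, -1]
  code <- a + 2 * b + 4 * cc + 8 * dd
  diag_len <- sqrt((sx / 2)^2 + (sy / 2)^2)
  # lengths by 2x2 pattern: single corner -> corner cut; adjacent pair ->
  # straight crossing; diagonal pair -> two corner cuts
  len <- c(0, diag_len, diag_len, sx, diag_len, sy, 2 * diag_len, diag_len,
           diag_len, 2 * diag_len, sy, diag_len, sx, diag_len, diag_len, 0)
  sum(len[code + 1])
}

# Deterministic sub-voxel jitter used to break grid coplanarity before the
# convex-hull computation; amplitude stays far below geometric tolerances
# and the fixed internal seed keeps extraction reproducible.
det_jitter <- function(n, amplitude) {
  with_seed(20260924,
            matrix(runif(3 * n, -amplitude, amplitude), ncol = 3))
}

#' Morphological features of a tumor mask
#'
#' The 12 shape descriptors: mesh surface area (marching tetrahedra over the
#' binary mask, mm^2), perimeter of the largest-area axial slice contour
#' (mm), concavity (1 - volume / convex-hull volume, hull taken over
#' boundary-voxel centres and clamped at 0), voxel count, maximum 3D diameter (largest pairwise distance
#' between boundary-voxel centres, mm), compactness1
#' `V / (sqrt(pi) A^(3/2))`, compactness2 `36 pi V^2 / A^3`, sphericity
#' `(36 pi V^2)^(1/3) / A`, surface-to-volume ratio, volume (mm^3),
#' major axis length (4 sqrt(lambda_1) from the voxel-coordinate PCA), and
#' elongation `sqrt(lambda_2 / lambda_1)`.
#'
#' Shape features should be computed on an (approximately) isotropic grid;
#' the perimeter uses the in-plane spacing of the axial (third-axis) slices.
#'
#' @param mask an [roi_mask()], a `voi` (its cropped mask is used), or a 3D
#'   logical array.
#' @param spacing_mm voxel spacing, used when `mask` is a bare array.
#' @return named numeric vector of length 12 (names `shape.*`).
#' @export
shape_features <- function(mask, spacing_mm = c(1, 1, 1)) {
  if (inherits(mask, "voi")) { m <- mask$mask; sp <- mask$spacing_mm }
  else if (inherits(mask, "roi_mask")) { m <- mask$voxels; sp <- mask$spacing_mm }
  else { m <- mask; sp <- spacing_mm }
  if (!any(m)) stop("empty-VOI error: mask has no foreground voxels")
  d <- dim(m)
  cnt <- sum(m)
  vol <- cnt * prod(sp)
  area <- mesh_surface_area(m, sp)
  bd <- boundary_voxels(m)
  bidx <- which(bd, arr.ind = TRUE)
  centres <- sweep(bidx - 1, 2, sp, `*`)
  maxdiam <- if (nrow(centres) > 1) cpp_max_pairwise(centres) else 0
  # concavity: rasterize the convex hull of the boundary-voxel centres on
  # the voxel grid (count centres inside it) so that digitization affects
  # solid and hull volume alike and cancels in the ratio
  all_centres <- sweep(which(array(TRUE, d), arr.ind = TRUE) - 1, 2, sp, `*`)
  n_hull <- cpp_convhull_inside_count(
    centres + det_jitter(nrow(centres), 0.02 * min(sp)),
    all_centres, 1e-6 * max(sp))
  concavity <- if (n_hull > 0) max(0, 1 - cnt / n_hull) else 0
  # largest-area axial slice
  slice_counts <- apply(m, 3, sum)
  zbest <- which.max(slice_counts)
  perim <- slice_perimeter(array(m[, , zbest], d[1:2]), sp[1], sp[2])
  # PCA of foreground voxel coordinates (population covariance)
  coords <- sweep(which(m, arr.ind = TRUE) - 1, 2, sp, `*`)
  if (cnt > 1) {
    cv <- crossprod(sweep(coords, 2, colMeans(coords))) / cnt
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  out <- c(
    surface_area = area,
    perimeter = perim,
    concavity = concavity,
    voxel_count = cnt,
    max_diameter_3d = maxdiam,
    compactness1 = vol / (sqrt(pi) * area^1.5),
    compactness2 = 36 * pi * vol^2 / area^3,
    sphericity = (36 * pi * vol^2)^(1 / 3) / area,
    surface_to_volume = area / vol,
    volume_mm3 = vol,
    major_axis_length = major,
    elongation = elong)
  names(out) <- paste0("shape.", SHAPE_NAMES)
  out
}
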