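# Texture matrices and their feature sets.
#
# All matrices are built on the discretized level array of a VOI (level 0 =
# outside). GLCM and GLRLM use the 13 unique 3D directions at distance 1;
# GLSZM/NGTDM/GLDM use the 26-neighbourhood. GLCM matrices are normalized
# per direction and averaged; GLRLM counts are merged (summed) across
# directions before feature computation.

#' The 13 unique 3D direction offsets
#'
#' One representative per antipodal pair of the 26-neighbourhood.
#'
#' @return 13 x 3 integer matrix of voxel offsets.
#' @export
direction_offsets_3d <- function() {
  matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1,
           1, 1, 0,  1, -1, 0,  1, 0, 1,  1, 0, -1,  0, 1, 1,  0, 1, -1,
           1, 1, 1,  1, 1, -1,  1, -1, 1,  -1, 1, 1),
         ncol = 3, byrow = TRUE)
}

#' Grey-level co-occurrence matrix
#'
#' Symmetric co-occurrence counts within the VOI at the given distance, one
#' matrix per direction, plus the direction-averaged normalized matrix. A
#' VOI with no valid voxel pair (single voxel) degenerates to a point mass
#' at its single level.
#'
#' @param voi a [make_voi()] object.
#' @param distance offset length in voxels (default 1).
#' @return list with `counts` (G x G x 13 array) and `P` (G x G averaged
#'   normalized matrix).
#' @export
glcm_matrix <- function(voi, distance = 1) {
  d <- dim(voi$levels)
  offs <- direction_offsets_3d() * as.integer(distance)
  counts <- cpp_glcm(as.integer(voi$levels), d[1], d[2], d[3],
                     voi$n_levels, offs)
  sums <- apply(counts, 3, sum)
  ng <- voi$n_levels
  if (all(sums == 0)) {
    P <- matrix(0, ng, ng)
    l1 <- voi$levels[voi$mask][1]
    P[l1, l1] <- 1
  } else {
    keep <- which(sums > 0)
    P <- Reduce(`+`, lapply(keep, function(k)
      matrix(counts[, , k], ng, ng) / sums[k])) / length(keep)
  }
  list(counts = counts, P = P)
}

#' Haralick/GLCM texture features
#'
#' The 25 co-occurrence features computed from a direction-averaged
#' normalized GLCM. Degenerate conventions for a single-level VOI:
#' correlation 1, information measures 0.
#'
#' @param P normalized G x G co-occurrence matrix (sums to 1), e.g.
#'   `glcm_matrix(voi)$P`.
#' @return named numeric vector of length 25.
#' @export
glcm_features <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  # diagonal / cross-diagonal distributions
  k_sum <- 2:(2 * ng)
  p_sum <- as.numeric(rowsum(as.vector(P), as.vector(i + j),
                             reorder = TRUE))
  k_dif <- 0:(ng - 1)
  p_dif <- numeric(ng)
  pd <- rowsum(as.vector(P), as.vector(abs(i - j)), reorder = TRUE)
  p_dif[as.integer(rownames(pd)) + 1] <- pd
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- ent(P)
  pxpy <- px[i] * px[j]
  hxy1 <- -sum(P[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- ent(pxpy)
  hx <- ent(px)
  da <- sum(k_dif * p_dif)
  sa <- sum(k_sum * p_sum)
  out <- c(
    autocorrelation = sum(i * j * P),
    joint_average = mu,
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1,
    difference_average = da,
    difference_entropy = ent(p_dif),
    difference_variance = sum((k_dif - da)^2 * p_dif),
    dissimilarity = sum(abs(i - j) * P),
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + ((i - j) / ng)^2)),
    id = sum(P / (1 + abs(i - j))),
    idn = sum(P / (1 + abs(i - j) / ng)),
    inverse_variance = sum((P / (i - j)^2)[i != j]),
    maximum_probability = max(P),
    sum_average = sa,
    sum_entropy = ent(p_sum),
    sum_squares = sum((i - mu)^2 * P),
    sum_variance = sum((k_sum - sa)^2 * p_sum))
  names(out) <- GLCM_NAMES
  out
}

#' Grey-level run-length features
#'
#' Counts maximal same-level runs along the 13 directions (merged across
#' directions) and computes the standard 16 run-length features.
#'
#' @param voi a [make_voi()] object.
#' @param return_counts if `TRUE`, also return the per-direction count
#'   array.
#' @return named numeric vector of length 16 (or a list when
#'   `return_counts`).
#' @export
glrlm_features <- function(voi, return_counts = FALSE) {
  d <- dim(voi$levels)
  counts <- cpp_glrlm(as.integer(voi$levels), d[1], d[2], d[3],
                      voi$n_levels, direction_offsets_3d(), max(d))
  R <- apply(counts, c(1, 2), sum)
  g <- row(R); r <- col(R)
  nr <- sum(R)
  np <- sum(r * R)
  p <- R / nr
  mug <- sum(g * p); mur <- sum(r * p)
  pp <- p[p > 0]
  out <- c(
    sre = sum(R / r^2) / nr,
    lre = sum(R * r^2) / nr,
    gln = sum(rowSums(R)^2) / nr,
    glnn = sum(rowSums(R)^2) / nr^2,
    rln = sum(colSums(R)^2) / nr,
    rlnn = sum(colSums(R)^2) / nr^2,
    run_percentage = nr / np,
    gl_variance = sum((g - mug)^2 * p),
    run_variance = sum((r - mur)^2 * p),
    run_entropy = -sum(pp * log2(pp)),
    lgre = sum(R / g^2) / nr,
    hgre = sum(R * g^2) / nr,
    srlge = sum(R / (g^2 * r^2)) / nr,
    srhge = sum(R * g^2 / r^2) / nr,
    lrlge = sum(R * r^2 / g^2) / nr,
    lrhge = sum(R * g^2 * r^2) / nr)
  names(out) <- GLRLM_NAMES
  if (return_counts) list(features = out, counts = counts) else out
}

#' Grey-level size-zone features
#'
#' Zones are 26-connected components of constant level; the 16 standard
#' size-zone features are computed from the (level, size) zone counts.
#'
#' @param voi a [make_voi()] object.
#' @param return_zones if `TRUE`, also return the (level, size) zone table.
#' @return named numeric vector of length 16 (or a list when
#'   `return_zones`).
#' @export
glszm_features <- function(voi, return_zones = FALSE) {
  d <- dim(voi$levels)
  zones <- cpp_glszm_zones(as.integer(voi$levels), d[1], d[2], d[3])
  g <- zones[, 1]; s <- zones[, 2]
  nz <- nrow(zones)
  np <- sum(s)
  # cell probabilities aggregate zones sharing (level, size)
  cell <- table(paste(g, s))
  pcell <- as.numeric(cell) / nz
  mug <- sum(g) / nz; mus <- sum(s) / nz
  out <- c(
    sae = sum(1 / s^2) / nz,
    lae = sum(s^2) / nz,
    gln = sum(tapply(rep(1, nz), g, sum)^2) / nz,
    glnn = sum(tapply(rep(1, nz), g, sum)^2) / nz^2,
    szn = sum(tapply(rep(1, nz), s, sum)^2) / nz,
    sznn = sum(tapply(rep(1, nz), s, sum)^2) / nz^2,
    zone_percentage = nz / np,
    gl_variance = sum((g - mug)^2) / nz,
    zone_variance = sum((s - mus)^2) / nz,
    zone_entropy = -sum(pcell * log2(pcell)),
    lglze = sum(1 / g^2) / nz,
    hglze = sum(g^2) / nz,
    salge = sum(1 / (g^2 * s^2)) / nz,
    sahge = sum(g^2 / s^2) / nz,
    lalge = sum(s^2 / g^2) / nz,
    lahge = sum(g^2 * s^2) / nz)
  names(out) <- GLSZM_NAMES
  if (return_zones) list(features = out, zones = zones) else out
}

#' Neighbourhood grey-tone difference features
#'
#' Per grey level, sums the absolute difference between the level and the
#' mean of the voxel's in-VOI 26-neighbours; yields coarseness, contrast,
#' busyness, complexity and strength. Coarseness is capped at 1e6 for
#' (near-)constant VOIs.
#'
#' @param voi a [make_voi()] object.
#' @return named numeric vector of length 5.
#' @export
ngtdm_features <- function(voi) {
  d <- dim(voi$levels)
  m <- cpp_ngtdm(as.integer(voi$levels), d[1], d[2], d[3], voi$n_levels)
  s <- m[, 1]; n <- m[, 2]
  ntot <- sum(n)
  if (ntot == 0)  # no voxel has an in-VOI neighbour (e.g. single voxel)
    return(c(coarseness = 1e6, contrast = 0, busyness = 0, complexity = 0,
             strength = 0))
  pres <- which(n > 0)
  p <- n / ntot
  ngp <- length(pres)
  lv <- seq_len(voi$n_levels)
  denom_coarse <- sum(p * s)
  ii <- rep(pres, times = ngp); jj <- rep(pres, each = ngp)
  contrast <- if (ngp > 1)
    sum(p[ii] * p[jj] * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(s) / ntot
  else 0
  busy_den <- sum(abs(ii * p[ii] - jj * p[jj]))
  complexity <- sum(abs(ii - jj) * (p[ii] * s[ii] + p[jj] * s[jj]) /
                      (p[ii] + p[jj])) / ntot
  strength <- if (sum(s) > 0) sum((p[ii] + p[jj]) * (ii - jj)^2) / sum(s)
  else 0
  c(coarseness = if (denom_coarse > 1e-6) min(1 / denom_coarse, 1e6) else 1e6,
    contrast = contrast,
    busyness = if (busy_den > 0) denom_coarse / busy_den else 0,
    complexity = complexity,
    strength = strength)
}

#' Grey-level dependence features
#'
#' For each VOI voxel, the dependence is the number of in-VOI 26-neighbours
#' whose level is within `alpha` of the centre level; the matrix of
#' (level, dependence) counts yields 14 features. Dependence size k in the
#' formulas is the neighbour count plus one.
#'
#' @param voi a [make_voi()] object.
#' @param alpha level-difference tolerance (default 0).
#' @return named numeric vector of length 14.
#' @export
gldm_features <- function(voi, alpha = 0) {
  d <- dim(voi$levels)
  P <- cpp_gldm(as.integer(voi$levels), d[1], d[2], d[3], voi$n_levels,
                as.integer(alpha))
  g <- row(P); k <- col(P)  # k = dependence + 1
  nz <- sum(P)
  p <- P / nz
  mug <- sum(g * p); muk <- sum(k * p)
  pp <- p[p > 0]
  out <- c(
    sde = sum(P / k^2) / nz,
    lde = sum(P * k^2) / nz,
    gln = sum(rowSums(P)^2) / nz,
    dn = sum(colSums(P)^2) / nz,
    dnn = sum(colSums(P)^2) / nz^2,
    gl_variance = sum((g - mug)^2 * p),
    dependence_variance = sum((k - muk)^2 * p),
    dependence_entropy = -sum(pp * log2(pp)),
    lgle = sum(P / g^2) / nz,
    hgle = sum(P * g^2) / nz,
    sdlge = sum(P / (g^2 * k^2)) / nz,
    sdhge = sum(P * g^2 / k^2) / nz,
    ldlge = sum(P * k^2 / g^2) / nz,
    ldhge = sum(P * g^2 * k^2) / nz)
  names(out) <- GLDM_NAMES
  out
}
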