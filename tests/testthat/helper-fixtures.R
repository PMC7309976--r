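# Small in-code fixtures shared across tests.

# Digital ball of radius r (voxels/mm at unit spacing) centred in its grid.
make_ball <- function(r, margin = 3) {
  n <- 2 * (r + margin) + 1
  d <- c(n, n, n)
  ctr <- (n - 1) / 2
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  array(rowSums(sweep(idx - 1, 2, rep(ctr, 3))^2) <= r^2, d)
}

# Build a VOI whose discretized levels equal `lv` exactly (0 = outside).
# bin_width = 1 on intensities equal to the levels gives level = x - min + 1,
# an identity whenever level 1 is present.
make_test_voi <- function(lv, spacing = c(1, 1, 1)) {
  lv <- as.array(lv)
  if (length(dim(lv)) == 2) dim(lv) <- c(dim(lv), 1)
  if (length(dim(lv)) == 1 || is.null(dim(lv))) dim(lv) <- c(length(lv), 1, 1)
  stopifnot(any(lv > 0), min(lv[lv > 0]) == 1)
  img <- image_volume(array(as.numeric(lv), dim(lv)), spacing)
  msk <- roi_mask(array(as.integer(lv > 0), dim(lv)), spacing)
  make_voi(img, msk, iso_spacing_mm = NULL, n_levels = NULL, bin_width = 1)
}

# Random small level array with background, for oracle-equivalence sweeps.
random_level_array <- function(dims, ng, p_bg = 0.3) {
  lv <- array(sample(0:ng, prod(dims), replace = TRUE,
                     prob = c(p_bg, rep((1 - p_bg) / ng, ng))), dims)
  if (!any(lv > 0)) lv[1] <- 1L
  # ensure level 1 present so make_test_voi keeps levels verbatim
  lv[which(lv > 0)[1]] <- 1L
  lv
}

# A tiny cohort spec for fast pipeline tests (not the study-scale default).
tiny_cohort_spec <- function(n_tnbc = 8, n_ntnbc = 8, seed = 1, ...) {
  cohort_spec(n_tnbc = n_tnbc, n_ntnbc = n_ntnbc, grid_shape = c(22, 22, 22),
              lesion_radius_range_mm = c(3.5, 5.5), seed = seed, ...)
}
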