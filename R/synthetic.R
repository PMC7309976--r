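# Synthetic two-class CT cohort generator.
#
# Each synthetic patient is one ellipsoidal lesion on a soft-tissue
# background: the lesion interior is spatially correlated Gaussian noise
# (class-specific correlation length, mean, sd) plus a low-frequency
# sinusoidal intensity band; the boundary is deformed by a smooth low-order
# radial perturbation (class-specific amplitude). A second "observer" mask
# simulates a radiologist's re-delineation by random one-step dilation or
# erosion of the primary mask.

#' Specification of a synthetic CT cohort
#'
#' Defaults emulate a 300-patient two-class cohort (100 TNBC / 200 NTNBC,
#' 60% discovery) whose classes differ in lesion texture (correlation
#' length, intensity statistics, band amplitude) and boundary irregularity.
#'
#' @param n_tnbc,n_ntnbc class sizes (total must be at least 4).
#' @param discovery_fraction proportion assigned to the discovery split,
#'   in (0, 1); the per-class discovery size is `round(fraction * n)`.
#' @param grid_shape voxels per axis.
#' @param voxel_spacing_mm voxel spacing, mm.
#' @param lesion_radius_range_mm min/max effective lesion radius, mm.
#' @param texture_params_per_class list with elements `TNBC` and `NTNBC`,
#'   each `list(correlation_length_mm, intensity_mean, intensity_sd,
#'   band_amplitude)`.
#' @param shape_irregularity_per_class named vector (TNBC, NTNBC) of radial
#'   perturbation amplitudes (relative; 0 = perfect ellipsoid).
#' @param observer_perturbation `list(dilate_erode_prob, max_margin_voxels)`
#'   controlling the simulated second delineation.
#' @param seed integer master seed; identical spec + seed reproduces the
#'   cohort bit for bit.
#' @return validated object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tnbc = 100, n_ntnbc = 200, discovery_fraction = 0.6,
                        grid_shape = c(30, 30, 30),
                        voxel_spacing_mm = c(1, 1, 1),
                        lesion_radius_range_mm = c(4, 8),
                        texture_params_per_class = list(
                          TNBC = list(correlation_length_mm = 3,
                                      intensity_mean = 70, intensity_sd = 20,
                                      band_amplitude = 15),
                          NTNBC = list(correlation_length_mm = 1.5,
                                       intensity_mean = 60, intensity_sd = 12,
                                       band_amplitude = 5)),
                        shape_irregularity_per_class = c(TNBC = 0.25,
                                                         NTNBC = 0.12),
                        observer_perturbation = list(dilate_erode_prob = 0.5,
                                                     max_margin_voxels = 1),
                        seed = 1) {
  spec <- structure(
    list(n_tnbc = as.integer(n_tnbc), n_ntnbc = as.integer(n_ntnbc),
         discovery_fraction = discovery_fraction,
         grid_shape = as.integer(grid_shape),
         voxel_spacing_mm = as.numeric(voxel_spacing_mm),
         lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
         texture_params_per_class = texture_params_per_class,
         shape_irregularity_per_class = shape_irregularity_per_class,
         observer_perturbation = observer_perturbation,
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_tnbc + spec$n_ntnbc < 4)
    stop("configuration error: cohort must have at least 4 patients")
  if (spec$discovery_fraction <= 0 || spec$discovery_fraction >= 1)
    stop("configuration error: discovery_fraction must be in (0, 1)")
  if (any(spec$voxel_spacing_mm <= 0) || any(spec$lesion_radius_range_mm <= 0))
    stop("configuration error: spacings and radii must be positive")
  if (any(spec$grid_shape < 3))
    stop("configuration error: grid too small")
  if (!all(c("TNBC", "NTNBC") %in% names(spec$texture_params_per_class)))
    stop("configuration error: texture parameters needed for TNBC and NTNBC")
  # the worst-case lesion (max radius, max outward perturbation, observer
  # dilation) must fit inside the grid
  max_irr <- max(spec$shape_irregularity_per_class)
  reach <- max(spec$lesion_radius_range_mm) * (1 + 1.5 * max_irr) +
    spec$observer_perturbation$max_margin_voxels * max(spec$voxel_spacing_mm)
  half_extent <- min((spec$grid_shape - 1) * spec$voxel_spacing_mm) / 2
  if (reach > half_extent - max(spec$voxel_spacing_mm))
    stop("configuration error: lesion cannot fit in grid (needs ",
         signif(reach, 3), " mm, half-extent ", signif(half_extent, 3), " mm)")
  invisible(spec)
}

# Separable Gaussian smoothing of a 3D array, kernel sd in voxels per axis.
gauss_smooth3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s < 0.3) next
    h <- max(1L, ceiling(3 * s))
    n <- d[a]
    S <- outer(seq_len(n), seq_len(n),
               function(i, j) dnorm(j - i, sd = s) * (abs(j - i) <= h))
    S <- S / rowSums(S)
    perm <- c(a, setdiff(1:3, a))
    x <- aperm(arr, perm)
    dm <- dim(x)
    x <- S %*% matrix(x, nrow = n)
    dim(x) <- dm
    arr <- aperm(x, order(perm))
  }
  arr
}

# One-voxel 6-neighbourhood dilation / erosion.
dilate6 <- function(m) {
  out <- m
  for (a in 1:3) for (b in c(-1, 1)) out <- out | shift_mask(m, a, b)
  out
}
erode6 <- function(m) {
  out <- m
  for (a in 1:3) for (b in c(-1, 1)) out <- out & shift_mask(m, a, b)
  out
}

#' Generate one synthetic lesion
#'
#' Returns the image, the primary lesion mask, and a perturbed "second
#' observer" mask for one synthetic patient of the given class.
#'
#' @param spec a [cohort_spec()].
#' @param class_label `"TNBC"` or `"NTNBC"`.
#' @param seed integer substream seed for this patient (defaults to the
#'   spec's master seed).
#' @return `list(image, mask, mask2)` of [image_volume()] and [roi_mask()]
#'   objects.
#' @export
generate_lesion <- function(spec, class_label = c("TNBC", "NTNBC"),
                            seed = spec$seed) {
  class_label <- match.arg(class_label)
  validate_cohort_spec(spec)
  tp <- spec$texture_params_per_class[[class_label]]
  irr <- unname(spec$shape_irregularity_per_class[[class_label]])
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  with_seed(seed, {
    centre <- (d - 1) * sp / 2 + runif(3, -0.5, 0.5) * sp
    r_eff <- runif(1, spec$lesion_radius_range_mm[1],
                   spec$lesion_radius_range_mm[2])
    ax <- runif(3, 0.8, 1.25)
    ax <- ax / prod(ax)^(1 / 3)          # geometric mean 1: volume ~ r_eff^3
    # smooth low-order radial perturbation of the unit sphere
    cf <- rnorm(8)
    cf <- cf / sqrt(sum(cf^2))
    gx <- (seq_len(d[1]) - 1) * sp[1] - centre[1]
    gy <- (seq_len(d[2]) - 1) * sp[2] - centre[2]
    gz <- (seq_len(d[3]) - 1) * sp[3] - centre[3]
    X <- array(gx, d)
    Y <- aperm(array(gy, d[c(2, 1, 3)]), c(2, 1, 3))
    Z <- aperm(array(gz, d[c(3, 2, 1)]), c(3, 2, 1))
    rx <- X / (ax[1] * r_eff); ry <- Y / (ax[2] * r_eff); rz <- Z / (ax[3] * r_eff)
    rho <- sqrt(rx^2 + ry^2 + rz^2)
    nz <- pmax(rho, 1e-9)
    ux <- rx / nz; uy <- ry / nz; uz <- rz / nz
    f <- cf[1] * ux + cf[2] * uy + cf[3] * uz +
      cf[4] * (ux^2 - 1 / 3) + cf[5] * (uy^2 - 1 / 3) +
      cf[6] * ux * uy + cf[7] * ux * uz + cf[8] * uy * uz
    mask <- rho <= 1 + irr * f
    mask[is.na(mask)] <- FALSE
    if (!any(mask)) mask[round(d[1] / 2), round(d[2] / 2), round(d[3] / 2)] <- TRUE
    # background: soft tissue with mild uncorrelated noise
    img <- 40 + array(rnorm(prod(d), sd = 3), d)
    # lesion interior: correlated noise, rescaled to the class sd, plus a
    # low-frequency sinusoidal band across the lesion
    noise <- array(rnorm(prod(d)), d)
    noise <- gauss_smooth3(noise, rep(tp$correlation_length_mm, 3) / sp)
    nsd <- sd(noise)
    if (nsd > 0) noise <- noise / nsd
    bdir <- rnorm(3); bdir <- bdir / sqrt(sum(bdir^2))
    phase <- runif(1, 0, 2 * pi)
    band <- tp$band_amplitude *
      sin(2 * pi * (X * bdir[1] + Y * bdir[2] + Z * bdir[3]) /
            (2 * r_eff) + phase)
    lesion <- tp$intensity_mean + tp$intensity_sd * noise + band
    img[mask] <- lesion[mask]
    # observer mask: random dilation/erosion by up to max_margin_voxels
    m2 <- mask
    op <- spec$observer_perturbation
    if (op$max_margin_voxels > 0 && runif(1) < op$dilate_erode_prob) {
      steps <- sample.int(op$max_margin_voxels, 1)
      grow <- runif(1) < 0.5
      for (k in seq_len(steps))
        m2 <- if (grow) dilate6(m2) else erode6(m2)
      if (!any(m2)) m2 <- mask  # erosion must not empty the delineation
    }
    list(image = image_volume(img, sp),
         mask = roi_mask(array(as.integer(mask), d), sp),
         mask2 = roi_mask(array(as.integer(m2), d), sp))
  })
}

# Stratified discovery/validation assignment and per-patient substream
# seeds, all drawn from the master seed.
cohort_plan <- function(spec) {
  n <- spec$n_tnbc + spec$n_ntnbc
  with_seed(spec$seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    label <- rep(c("TNBC", "NTNBC"), c(spec$n_tnbc, spec$n_ntnbc))
    split <- character(n)
    for (cl in c("TNBC", "NTNBC")) {
      idx <- which(label == cl)
      ndisc <- round(spec$discovery_fraction * length(idx))
      disc <- sample(idx, ndisc)
      split[disc] <- "discovery"
      split[setdiff(idx, disc)] <- "validation"
    }
    data.frame(patient_id = sprintf("P%03d", seq_len(n)), label = label,
               split = split, seed = seeds, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic cohort
#'
#' Draws one lesion per patient with per-patient substream seeds derived
#' from the master seed (so any single patient can be regenerated), assigns
#' a stratified discovery/validation split, and either writes NIfTI images
#' and masks plus a manifest CSV to `dir`, or returns everything in memory
#' when `dir` is `NULL`.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory, or `NULL` for an in-memory cohort.
#' @return When writing: the manifest data.frame (`patient_id`, `label`,
#'   `split`, `image_path`, `mask_path`, `mask2_path`; paths relative to
#'   `dir`), invisibly; the manifest CSV is at `file.path(dir,
#'   "manifest.csv")`. In memory: `list(manifest, patients)` where
#'   `patients` is a list of [generate_lesion()] results.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  validate_cohort_spec(spec)
  plan <- cohort_plan(spec)
  if (is.null(dir)) {
    patients <- lapply(seq_len(nrow(plan)), function(i)
      generate_lesion(spec, plan$label[i], seed = plan$seed[i]))
    names(patients) <- plan$patient_id
    return(list(manifest = plan[, c("patient_id", "label", "split")],
                patients = patients))
  }
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("I/O error: cannot create output directory ", dir)
  manifest <- plan[, c("patient_id", "label", "split")]
  manifest$image_path <- paste0(plan$patient_id, "_image.nii.gz")
  manifest$mask_path <- paste0(plan$patient_id, "_mask.nii.gz")
  manifest$mask2_path <- paste0(plan$patient_id, "_mask2.nii.gz")
  for (i in seq_len(nrow(plan))) {
    les <- generate_lesion(spec, plan$label[i], seed = plan$seed[i])
    write_volume(les$image, file.path(dir, manifest$image_path[i]))
    write_volume(les$mask, file.path(dir, manifest$mask_path[i]))
    write_volume(les$mask2, file.path(dir, manifest$mask2_path[i]))
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Simulate a cohort and extract its feature table in memory
#'
#' Convenience wrapper for desk-scale experiments: generates the cohort of
#' `spec` without touching disk and runs [extract_features()] on every
#' patient's primary mask.
#'
#' @param spec a [cohort_spec()].
#' @param ... passed to [extract_features()].
#' @return data.frame: `patient_id`, `label`, `split`, then the 182 feature
#'   columns.
#' @export
simulate_cohort_features <- function(spec, ...) {
  plan <- cohort_plan(spec)
  feats <- lapply(seq_len(nrow(plan)), function(i) {
    les <- generate_lesion(spec, plan$label[i], seed = plan$seed[i])
    extract_features(les$image, les$mask, ...)
  })
  cbind(plan[, c("patient_id", "label", "split")],
        as.data.frame(do.call(rbind, feats)))
}
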