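# Synthetic cohort generator: determinism, split arithmetic, observer
# perturbation and validation errors.

test_that("identical spec and seed regenerate identical lesions", {
  spec <- tiny_cohort_spec()
  a <- generate_lesion(spec, "TNBC", seed = 42)
  b <- generate_lesion(spec, "TNBC", seed = 42)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_identical(a$mask2$voxels, b$mask2$voxels)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(generate_lesion(spec, "TNBC", seed = 1))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("zero perturbation makes the observer mask identical to the primary", {
  spec <- tiny_cohort_spec(
    observer_perturbation = list(dilate_erode_prob = 0.5,
                                 max_margin_voxels = 0))
  for (s in 1:5) {
    les <- generate_lesion(spec, "NTNBC", seed = s)
    expect_identical(les$mask$voxels, les$mask2$voxels)
  }
  # with perturbation on, some seeds must differ
  spec2 <- tiny_cohort_spec(
    observer_perturbation = list(dilate_erode_prob = 1,
                                 max_margin_voxels = 1))
  diffs <- vapply(1:10, function(s) {
    les <- generate_lesion(spec2, "NTNBC", seed = s)
    sum(les$mask$voxels != les$mask2$voxels)
  }, 0)
  expect_gt(sum(diffs > 0), 0)
})

test_that("study-scale split arithmetic gives 300 = 180 discovery + 120 validation", {
  spec <- cohort_spec(n_tnbc = 100, n_ntnbc = 200, discovery_fraction = 0.6)
  plan <- radsig:::cohort_plan(spec)
  expect_identical(nrow(plan), 300L)
  expect_identical(sum(plan$split == "discovery"), 180L)
  expect_identical(sum(plan$split == "validation"), 120L)
  # stratified: per-class counts match round(fraction * n)
  expect_identical(sum(plan$split == "discovery" & plan$label == "TNBC"), 60L)
  expect_identical(sum(plan$split == "discovery" & plan$label == "NTNBC"),
                   120L)
})

test_that("minimal 2+2 cohort keeps a patient of each class per split", {
  spec <- cohort_spec(n_tnbc = 2, n_ntnbc = 2, discovery_fraction = 0.5,
                      grid_shape = c(22, 22, 22),
                      lesion_radius_range_mm = c(3.5, 5))
  plan <- radsig:::cohort_plan(spec)
  expect_identical(nrow(plan), 4L)
  tab <- table(plan$label, plan$split)
  expect_true(all(tab == 1))
})

test_that("cohort writing is reproducible and manifests are complete", {
  spec <- tiny_cohort_spec(n_tnbc = 2, n_ntnbc = 3, seed = 9)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  m1 <- generate_cohort(spec, d1)
  m2 <- generate_cohort(spec, d2)
  expect_identical(m1, m2)
  expect_identical(nrow(m1), 5L)
  expect_true(all(c("patient_id", "label", "split", "image_path",
                    "mask_path", "mask2_path") %in% colnames(m1)))
  expect_true(all(file.exists(file.path(d1, m1$image_path))))
  # round-trip one patient bit-for-bit
  img <- read_volume(file.path(d1, m1$image_path[1]))
  img2 <- read_volume(file.path(d2, m2$image_path[1]))
  expect_identical(img$voxels, img2$voxels)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a lesion that cannot fit in the grid is a configuration error", {
  expect_error(cohort_spec(grid_shape = c(12, 12, 12),
                           lesion_radius_range_mm = c(4, 8)),
               "cannot fit")
  expect_error(cohort_spec(n_tnbc = 1, n_ntnbc = 1), "at least 4")
  expect_error(cohort_spec(discovery_fraction = 1), "discovery_fraction")
})

test_that("doubling the correlation length plants a large-zone texture effect", {
  # classes identical except TNBC correlation length = 2x NTNBC: the
  # size-zone large-area emphasis must separate them
  spec <- cohort_spec(
    texture_params_per_class = list(
      TNBC = list(correlation_length_mm = 3, intensity_mean = 60,
                  intensity_sd = 15, band_amplitude = 5),
      NTNBC = list(correlation_length_mm = 1.5, intensity_mean = 60,
                   intensity_sd = 15, band_amplitude = 5)),
    shape_irregularity_per_class = c(TNBC = 0.15, NTNBC = 0.15))
  lae <- function(cl, s) {
    les <- generate_lesion(spec, cl, seed = s)
    glszm_features(make_voi(les$image, les$mask))[["lae"]]
  }
  x_t <- vapply(1:50, function(s) lae("TNBC", s), 0)
  x_n <- vapply(1:50, function(s) lae("NTNBC", s + 1000), 0)
  p <- wilcox.test(x_t, x_n)$p.value
  expect_lt(p, 0.01)
  expect_gt(median(x_t), median(x_n))
})
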