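# Texture matrices: hand-enumerated examples, construction invariants,
# degenerate conventions, rotation coherence and shift invariance.

test_that("GLCM of a 2x2 slab matches hand enumeration", {
  # [[1,1],[2,2]] single slice; horizontal offset (1,0,0) pairs: (1,1), (2,2)
  lv <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))  # column-major: x varies first
  v <- make_test_voi(lv)
  d <- dim(v$levels)
  counts <- radsig:::cpp_glcm(as.integer(v$levels), d[1], d[2], d[3],
                              v$n_levels, matrix(c(1L, 0L, 0L), 1))
  P <- counts[, , 1] / sum(counts[, , 1])
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2))
  f <- glcm_features(P)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["joint_energy"]), 0.5)
})

test_that("GLCM is symmetric and normalizes to 1 per direction", {
  set.seed(7)
  lv <- random_level_array(c(6, 5, 4), ng = 5)
  v <- make_test_voi(lv)
  g <- glcm_matrix(v)
  for (k in seq_len(dim(g$counts)[3])) {
    M <- g$counts[, , k]
    expect_identical(M, t(M))
  }
  expect_equal(sum(g$P), 1, tolerance = 1e-12)
})

test_that("constant VOI follows the degenerate GLCM conventions", {
  v <- make_test_voi(array(1L, c(3, 3, 3)))
  f <- glcm_features(glcm_matrix(v)$P)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["correlation"]), 1)
  expect_equal(unname(f["joint_entropy"]), 0)
})

test_that("run enumeration matches the 1D hand example", {
  # row [1,1,2,1]: horizontal runs (1,len2), (2,len1), (1,len1)
  lv <- array(c(1L, 1L, 2L, 1L), c(4, 1, 1))
  v <- make_test_voi(lv)
  out <- glrlm_features(v, return_counts = TRUE)
  R <- out$counts[, , 1]  # first direction is (1,0,0)
  expect_equal(R[1, 2], 1)  # level 1, length 2
  expect_equal(R[1, 1], 1)  # level 1, length 1
  expect_equal(R[2, 1], 1)  # level 2, length 1
  expect_equal(sum(R), 3)
})

test_that("run-length mass per direction equals the voxel count", {
  set.seed(21)
  for (rep in 1:3) {
    lv <- random_level_array(c(5, 5, 4), ng = 4)
    v <- make_test_voi(lv)
    counts <- glrlm_features(v, return_counts = TRUE)$counts
    n <- v$voxel_count
    for (k in seq_len(dim(counts)[3])) {
      R <- counts[, , k]
      expect_equal(sum(sweep(R, 2, seq_len(ncol(R)), `*`)), n)
    }
  }
})

test_that("GLSZM zone mass equals voxel count; one-zone case is exact", {
  # single 26-connected region at one level
  lv <- array(0L, c(5, 5, 5)); lv[2:4, 2:4, 2:4] <- 1L
  v <- make_test_voi(lv)
  out <- glszm_features(v, return_zones = TRUE)
  expect_identical(nrow(out$zones), 1L)
  expect_identical(out$zones[1, ], c(1L, 27L))
  expect_equal(unname(out$features["zone_percentage"]), 1 / 27)
  set.seed(31)
  for (rep in 1:3) {
    lv <- random_level_array(c(6, 5, 4), ng = 4)
    v <- make_test_voi(lv)
    zones <- glszm_features(v, return_zones = TRUE)$zones
    expect_equal(sum(zones[, 2]), v$voxel_count)
  }
})

test_that("constant VOI caps NGTDM coarseness and zeroes contrast", {
  v <- make_test_voi(array(1L, c(4, 4, 4)))
  f <- ngtdm_features(v)
  expect_equal(unname(f["coarseness"]), 1e6)
  expect_equal(unname(f["contrast"]), 0)
})

test_that("rotating a VOI by 90 degrees leaves direction-averaged features unchanged", {
  set.seed(12)
  lv <- random_level_array(c(6, 6, 6), ng = 5)
  rot <- aperm(lv[, dim(lv)[2]:1, ], c(2, 1, 3))  # 90-degree turn about z
  v1 <- make_test_voi(lv); v2 <- make_test_voi(rot)
  expect_equal(glcm_features(glcm_matrix(v1)$P),
               glcm_features(glcm_matrix(v2)$P), tolerance = 1e-10)
  expect_equal(glrlm_features(v1), glrlm_features(v2), tolerance = 1e-10)
  expect_equal(glszm_features(v1), glszm_features(v2), tolerance = 1e-10)
  expect_equal(ngtdm_features(v1), ngtdm_features(v2), tolerance = 1e-10)
  expect_equal(gldm_features(v1), gldm_features(v2), tolerance = 1e-10)
})

test_that("intensity shift leaves texture invariant, shifts first-order mean", {
  spec <- tiny_cohort_spec()
  les <- generate_lesion(spec, "TNBC", seed = 3)
  f1 <- extract_features(les$image, les$mask)
  shifted <- image_volume(les$image$voxels + 100, les$image$spacing_mm)
  f2 <- extract_features(shifted, les$mask)
  tex <- grep("^(glcm|glrlm|glszm|ngtdm|gldm)\\.", names(f1), value = TRUE)
  expect_equal(f1[tex], f2[tex], tolerance = 1e-9)
  expect_equal(f2[["firstorder.mean"]], f1[["firstorder.mean"]] + 100,
               tolerance = 1e-9)
  expect_equal(f2[["firstorder.variance"]], f1[["firstorder.variance"]],
               tolerance = 1e-9)
})
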