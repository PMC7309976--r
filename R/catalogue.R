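# The fixed, ordered 182-feature catalogue.
#
# Layout: 18 first-order + 12 shape + 2 discretizations (G = 32 and G = 64)
# x (25 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM) = 182. Texture
# features are computed at both grey-level counts; first-order histogram
# statistics use the primary discretization (G = 32).

CATALOGUE_VERSION <- "1.0"

FIRSTORDER_NAMES <- c(
  "energy", "entropy", "minimum", "maximum", "mean", "median", "mad", "rms",
  "sd", "skewness", "kurtosis", "variance", "uniformity",
  "p10", "p90", "iqr", "range", "robust_mad")

SHAPE_NAMES <- c(
  "surface_area", "perimeter", "concavity", "voxel_count", "max_diameter_3d",
  "compactness1", "compactness2", "sphericity", "surface_to_volume",
  "volume_mm3", "major_axis_length", "elongation")

GLCM_NAMES <- c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "dissimilarity",
  "joint_energy", "joint_entropy", "imc1", "imc2", "idm", "idmn", "id",
  "idn", "inverse_variance", "maximum_probability", "sum_average",
  "sum_entropy", "sum_squares", "sum_variance")

GLRLM_NAMES <- c(
  "sre", "lre", "gln", "glnn", "rln", "rlnn", "run_percentage",
  "gl_variance", "run_variance", "run_entropy", "lgre", "hgre", "srlge",
  "srhge", "lrlge", "lrhge")

GLSZM_NAMES <- c(
  "sae", "lae", "gln", "glnn", "szn", "sznn", "zone_percentage",
  "gl_variance", "zone_variance", "zone_entropy", "lglze", "hglze",
  "salge", "sahge", "lalge", "lahge")

NGTDM_NAMES <- c("coarseness", "contrast", "busyness", "complexity",
                 "strength")

GLDM_NAMES <- c(
  "sde", "lde", "gln", "dn", "dnn", "gl_variance", "dependence_variance",
  "dependence_entropy", "lgle", "hgle", "sdlge", "sdhge", "ldlge", "ldhge")

#' The fixed radiomic feature catalogue
#'
#' Returns the ordered definition of the 182-feature catalogue: feature id,
#' family (`firstorder`, `shape`, `glcm`, `glrlm`, `glszm`, `ngtdm`,
#' `gldm`), and the grey-level count at which texture features are computed
#' (`NA` for first-order and shape). Ids are `family.name` or
#' `family.name.gG`.
#'
#' @return A data.frame with columns `id`, `family`, `name`, `n_levels`.
#' @export
feature_catalogue <- function() {
  rows <- list(
    data.frame(family = "firstorder", name = FIRSTORDER_NAMES,
               n_levels = NA_integer_),
    data.frame(family = "shape", name = SHAPE_NAMES, n_levels = NA_integer_))
  fams <- list(glcm = GLCM_NAMES, glrlm = GLRLM_NAMES, glszm = GLSZM_NAMES,
               ngtdm = NGTDM_NAMES, gldm = GLDM_NAMES)
  for (g in c(32L, 64L))
    for (f in names(fams))
      rows[[length(rows) + 1L]] <-
        data.frame(family = f, name = fams[[f]], n_levels = g)
  out <- do.call(rbind, rows)
  out$id <- ifelse(is.na(out$n_levels),
                   paste(out$family, out$name, sep = "."),
                   paste0(out$family, ".", out$name, ".g", out$n_levels))
  rownames(out) <- NULL
  out[, c("id", "family", "name", "n_levels")]
}

#' Serialize the feature catalogue as JSON
#'
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(path) {
  cat_df <- feature_catalogue()
  jsonlite::write_json(
    list(version = CATALOGUE_VERSION, n_features = nrow(cat_df),
         features = cat_df),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
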