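#' Extract the full 182-feature radiomic vector
#'
#' Runs the fixed catalogue over one image/mask pair: first-order and shape
#' features once, and the five texture families (GLCM, GLRLM, GLSZM, NGTDM,
#' GLDM) at the catalogue's two grey-level discretizations (G = 32 and
#' G = 64). All values are finite; degenerate VOIs follow the documented
#' conventions.
#'
#' @param image an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @param iso_spacing_mm isotropic resampling target in mm (`NULL` keeps
#'   the native grid). Default 1.
#' @param resegment_range optional intensity window applied to the
#'   foreground, see [make_voi()].
#' @param glcm_distance co-occurrence offset length in voxels.
#' @param gldm_alpha dependence level tolerance.
#' @return named numeric vector of length 182, in catalogue order.
#' @export
extract_features <- function(image, mask, iso_spacing_mm = 1,
                             resegment_range = NULL, glcm_distance = 1,
                             gldm_alpha = 0) {
  voi <- make_voi(image, mask, iso_spacing_mm = iso_spacing_mm,
                  n_levels = 32, resegment_range = resegment_range)
  out <- c(firstorder_features(voi),
           shape_features(voi$mask, voi$spacing_mm))
  for (g in c(32L, 64L)) {
    v <- if (g == 32L) voi else rediscretize(voi, g)
    tex <- c(glcm_features(glcm_matrix(v, distance = glcm_distance)$P),
             glrlm_features(v),
             glszm_features(v),
             ngtdm_features(v),
             gldm_features(v, alpha = gldm_alpha))
    names(tex) <- paste0(
      rep(c("glcm", "glrlm", "glszm", "ngtdm", "gldm"),
          times = c(25, 16, 16, 5, 14)),
      ".", c(GLCM_NAMES, GLRLM_NAMES, GLSZM_NAMES, NGTDM_NAMES, GLDM_NAMES),
      ".g", g)
    out <- c(out, tex)
  }
  cat_ids <- feature_catalogue()$id
  out <- out[cat_ids]
  if (any(!is.finite(out)))
    stop("non-finite feature values: ",
         paste(cat_ids[!is.finite(out)], collapse = ", "))
  out
}

#' Extract features for a whole cohort
#'
#' Applies [extract_features()] to every row of a cohort manifest (as
#' written by [generate_cohort()]): columns `patient_id`, `label`, `split`,
#' `image_path`, `mask_path`, `mask2_path`. Relative paths are resolved
#' against `base_dir`.
#'
#' @param manifest data.frame or path to the manifest CSV.
#' @param base_dir directory against which relative paths resolve; defaults
#'   to the manifest's directory when `manifest` is a path.
#' @param which_mask `"mask"` (primary) or `"mask2"` (second observer).
#' @param ... passed to [extract_features()].
#' @return data.frame: `patient_id`, `label`, `split`, then the 182 feature
#'   columns.
#' @export
extract_cohort <- function(manifest, base_dir = NULL, which_mask = "mask",
                           ...) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  base_dir <- base_dir %||% "."
  col <- if (which_mask == "mask") "mask_path" else "mask2_path"
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))
  feats <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_volume(resolve(manifest$image_path[i]))
    msk <- read_mask(resolve(manifest[[col]][i]), img)
    extract_features(img, msk, ...)
  })
  cbind(manifest[, c("patient_id", "label", "split")],
        as.data.frame(do.call(rbind, feats)))
}
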