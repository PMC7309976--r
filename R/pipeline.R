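# Config-driven orchestration: simulate -> extract -> ICC -> select/fit ->
# score -> evaluate, with a reproducible run manifest.

default_run_config <- function() {
  list(
    cohort = list(synthetic_spec = NULL, manifest = NULL),
    output_dir = NULL,
    preprocessing = list(iso_spacing_mm = 1, resegment_range = NULL),
    filtering = list(variance_threshold = 0),
    rfe = list(enabled = TRUE, k = 30, seed = 7),
    lasso = list(n_folds = 10, lambda_rule = "min", seed = 7),
    evaluation = list(icc_form = "icc2_1", icc_n = 30),
    signature = list(source = "fit", file = NULL))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline run configuration
#'
#' Reads a YAML (or JSON) configuration and fills unspecified fields with
#' package defaults. The `cohort` section names either a
#' `synthetic_spec` (fields of [cohort_spec()]) or an existing `manifest`
#' CSV.
#'
#' @param path YAML/JSON file, or a list to merge with defaults.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  merge_config(default_run_config(), cfg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full radiomics analysis pipeline
#'
#' Executes, in order: cohort acquisition (synthetic generation or an
#' existing manifest), feature extraction, observer-agreement ICC on a
#' subset of discovery patients (both delineations), signature construction
#' (fitted on the discovery split, loaded from file, or the published
#' model), scoring of every patient with discovery-learned parameters only,
#' and diagnostic evaluation of both splits at the discovery-learned Youden
#' cutoff. All artifacts land in `output_dir`: `features.csv`, `icc.csv`,
#' `signature.json`, `scores.csv`, `report_discovery.json`,
#' `report_validation.json`, `run_manifest.json` (plus `data/` when the
#' cohort is synthetic).
#'
#' @param config a configuration list or path, see [read_run_config()].
#' @return invisibly, `list(signature, reports, icc_summary, scores,
#'   features, paths)`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out <- cfg$output_dir
  if (is.null(out)) stop("config error: output_dir is required")
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop("config error: cannot create output_dir ", out)

  manifest <- run_stage("cohort", {
    if (!is.null(cfg$cohort$synthetic_spec)) {
      spec <- do.call(cohort_spec, cfg$cohort$synthetic_spec)
      generate_cohort(spec, file.path(out, "data"))
    } else if (!is.null(cfg$cohort$manifest)) {
      read.csv(cfg$cohort$manifest, stringsAsFactors = FALSE)
    } else stop("config error: cohort needs synthetic_spec or manifest")
  })
  data_dir <- if (!is.null(cfg$cohort$synthetic_spec)) file.path(out, "data")
              else dirname(cfg$cohort$manifest %||% ".")

  features <- run_stage("extract", {
    ft <- extract_cohort(manifest, base_dir = data_dir,
                         iso_spacing_mm = cfg$preprocessing$iso_spacing_mm,
                         resegment_range = cfg$preprocessing$resegment_range)
    write.csv(ft, file.path(out, "features.csv"), row.names = FALSE)
    ft
  })

  icc_summary <- run_stage("icc", {
    disc_rows <- which(manifest$split == "discovery")
    nsub <- min(cfg$evaluation$icc_n, length(disc_rows))
    sub <- manifest[disc_rows[seq_len(nsub)], , drop = FALSE]
    f2 <- extract_cohort(sub, base_dir = data_dir, which_mask = "mask2",
                         iso_spacing_mm = cfg$preprocessing$iso_spacing_mm,
                         resegment_range = cfg$preprocessing$resegment_range)
    f1 <- features[match(sub$patient_id, features$patient_id), , drop = FALSE]
    ids <- feature_catalogue()$id
    per_feature <- vapply(ids, function(id) {
      m <- cbind(f1[[id]], f2[[id]])
      if (pop_var(as.numeric(m)) < 1e-12) return(NA_real_)
      suppressWarnings(icc(m, form = cfg$evaluation$icc_form)$icc)
    }, 0)
    df <- data.frame(id = ids, icc = per_feature)
    write.csv(df, file.path(out, "icc.csv"), row.names = FALSE)
    ok <- per_feature[is.finite(per_feature)]
    list(n_subjects = as.integer(nsub), form = cfg$evaluation$icc_form,
         median = median(ok), min = min(ok), max = max(ok),
         fraction_reliable = mean(ok > 0.75))
  })

  feat_cols <- feature_catalogue()$id
  y <- as.integer(features$label == "TNBC")
  disc <- features$split == "discovery"
  if (!any(y[disc] == 1) || !any(y[disc] == 0))
    stop("stage 'signature' failed: both classes required in discovery split")

  model <- run_stage("signature", {
    src <- cfg$signature$source
    if (src == "fit") {
      radiomic_signature(
        features[disc, feat_cols], y[disc],
        variance_threshold = cfg$filtering$variance_threshold,
        rfe = isTRUE(cfg$rfe$enabled), rfe_k = cfg$rfe$k,
        nfolds = cfg$lasso$n_folds, lambda_rule = cfg$lasso$lambda_rule,
        seed = cfg$lasso$seed)
    } else if (src == "published") published_signature()
    else if (src == "file") read_signature(cfg$signature$file)
    else stop("config error: unknown signature source ", src)
  })
  write_signature(model, file.path(out, "signature.json"))

  scores <- run_stage("score", {
    s <- radiomics_score(model, features[, setdiff(colnames(features),
                                                   c("patient_id", "label",
                                                     "split"))])
    df <- data.frame(patient_id = features$patient_id,
                     label = features$label, split = features$split,
                     score = s)
    write.csv(df, file.path(out, "scores.csv"), row.names = FALSE)
    df
  })

  reports <- run_stage("evaluate", {
    cutoff <- optimal_cutoff(scores$score[disc], y[disc])
    rd <- diagnostic_report(scores$score[disc], y[disc], cutoff,
                            cohort = "discovery")
    rv <- diagnostic_report(scores$score[!disc], y[!disc], cutoff,
                            cohort = "validation")
    jsonlite::write_json(report_to_list(rd),
                         file.path(out, "report_discovery.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report_to_list(rv),
                         file.path(out, "report_validation.json"),
                         auto_unbox = TRUE, digits = NA)
    list(discovery = rd, validation = rv)
  })

  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("radsig")),
    catalogue_version = CATALOGUE_VERSION,
    config = cfg,
    icc_summary = icc_summary,
    timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out, "run_manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(signature = model, reports = reports,
                 icc_summary = icc_summary, scores = scores,
                 features = features,
                 paths = list(output_dir = out)))
}
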