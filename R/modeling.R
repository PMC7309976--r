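# Feature filtering, normalization and SVM-RFE ranking.

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Variance filter
#'
#' Retains features whose raw-scale (pre-normalization) variance on the
#' discovery data strictly exceeds the threshold. With the default
#' threshold 0 this drops constant columns only. Variances use the
#' population (n) denominator.
#'
#' @param x feature matrix or data.frame (rows = patients).
#' @param threshold nonnegative variance threshold.
#' @return character vector of retained feature names, in input order.
#' @export
variance_filter <- function(x, threshold = 0) {
  x <- as_feature_matrix(x)
  if (nrow(x) == 0) stop("discovery split is empty")
  v <- apply(x, 2, pop_var)
  keep <- colnames(x)[v > threshold]
  if (length(keep) == 0)
    stop("degenerate-filter error: no features exceed variance threshold ",
         threshold)
  keep
}

#' Learn z-score normalization parameters
#'
#' Per-feature mean and population standard deviation, learned on the
#' discovery split only; apply to any split with [zscore_apply()].
#'
#' @param x discovery feature matrix.
#' @return `list(mean, sd)` of named numeric vectors (class
#'   `zscore_params`).
#' @export
zscore_fit <- function(x) {
  x <- as_feature_matrix(x)
  mu <- colMeans(x)
  sdv <- sqrt(apply(x, 2, pop_var))
  if (any(sdv == 0))
    stop("zero-variance feature(s) reached normalization (filter first): ",
         paste(colnames(x)[sdv == 0], collapse = ", "))
  structure(list(mean = mu, sd = sdv), class = "zscore_params")
}

#' Apply z-score normalization
#'
#' @param x feature matrix (any split); must contain every feature named in
#'   `params`.
#' @param params a [zscore_fit()] object.
#' @return normalized matrix over the features in `params`, in their order.
#' @export
zscore_apply <- function(x, params) {
  x <- as_feature_matrix(x)
  miss <- setdiff(names(params$mean), colnames(x))
  if (length(miss))
    stop("missing features: ", paste(miss, collapse = ", "))
  x <- x[, names(params$mean), drop = FALSE]
  sweep(sweep(x, 2, params$mean), 2, params$sd, `/`)
}

# Stratified fold assignment (both classes in every fold).
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' SVM-based recursive feature elimination
#'
#' Ranks features by recursive elimination with an RBF-kernel support
#' vector machine (defaults C = 0.78, gamma = 0.00069). Because an RBF
#' kernel has no native coefficient vector, per-feature importance within
#' each round is the permutation importance: the drop in cross-validated
#' accuracy when that feature's values are permuted in the held-out fold.
#' Each round eliminates the lowest-scoring `step_fraction` of the current
#' features until `target_k` remain. Deterministic for a fixed seed.
#'
#' @param x normalized discovery feature matrix.
#' @param y binary labels (positive class = 1).
#' @param target_k number of features to retain.
#' @param step_fraction fraction eliminated per round (default 0.1).
#' @param cost,gamma RBF-SVM hyperparameters.
#' @param n_folds folds for the permutation-importance CV (default 5).
#' @param seed RNG seed for folds and permutations.
#' @return `list(ranking, selected, importance)`: `ranking` orders all
#'   features best to worst, `selected` is the retained top `target_k`,
#'   `importance` the final-round scores.
#' @export
svm_rfe_rank <- function(x, y, target_k = 30, step_fraction = 0.1,
                         cost = 0.78, gamma = 0.00069, n_folds = 5,
                         seed = 1) {
  x <- as_feature_matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (ncol(x) < 2) stop("need at least 2 features")
  if (target_k >= ncol(x)) {
    warning("target_k >= feature count: no-op, single scoring pass only")
    target_k <- ncol(x)
  }
  eliminated <- character(0)
  current <- colnames(x)
  importance <- NULL
  perm_importance <- function(current) {
    fold <- stratified_folds(y, n_folds)
    score <- numeric(length(current))
    names(score) <- current
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- e1071::svm(x[tr, current, drop = FALSE], factor(y[tr]),
                        kernel = "radial", cost = cost, gamma = gamma,
                        scale = FALSE)
      xt <- x[!tr, current, drop = FALSE]
      base_acc <- mean(predict(fit, xt) == y[!tr])
      perm <- sample(nrow(xt))
      for (j in current) {
        xp <- xt
        xp[, j] <- xp[perm, j]
        score[j] <- score[j] + (base_acc - mean(predict(fit, xp) == y[!tr]))
      }
    }
    score / n_folds
  }
  with_seed(seed, {
    repeat {
      score <- perm_importance(current)
      if (length(current) == target_k) { importance <- score; break }
      n_drop <- min(max(1L, floor(step_fraction * length(current))),
                    length(current) - target_k)
      drop <- names(sort(score))[seq_len(n_drop)]
      eliminated <- c(drop, eliminated)  # later-eliminated ranks higher
      current <- setdiff(current, drop)
    }
  })
  list(ranking = c(names(sort(importance, decreasing = TRUE)), eliminated),
       selected = names(sort(importance, decreasing = TRUE)),
       importance = importance)
}
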