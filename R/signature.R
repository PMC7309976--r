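#' Fit a radiomics signature by penalized logistic regression
#'
#' The package's central estimator. On the discovery data it (1) removes
#' low-variance features ([variance_filter()]), (2) z-score-normalizes with
#' discovery-learned parameters ([zscore_fit()]), (3) optionally pre-ranks
#' features by SVM recursive elimination ([svm_rfe_rank()]) and keeps the
#' top `rfe_k`, and (4) fits an L1-penalized (LASSO) logistic regression
#' over a log-spaced lambda grid with stratified k-fold cross-validation,
#' choosing the lambda that minimizes mean cross-validated binomial
#' deviance (or the one-standard-error rule). The signature is the
#' intercept plus the non-zero coefficients of the full-discovery fit at
#' the chosen lambda; the radiomics score of a patient is the
#' coefficient-weighted sum of their (normalized) features.
#'
#' @param x discovery feature matrix or data.frame (rows = patients,
#'   columns = named features, raw scale).
#' @param y binary labels; the positive class (TNBC) is 1 (or the second
#'   factor level).
#' @param variance_threshold raw-scale variance threshold (default 0:
#'   constants only).
#' @param rfe run SVM-RFE pre-ranking? Default `TRUE`.
#' @param rfe_k features retained by RFE before the LASSO (default 30).
#' @param nfolds cross-validation folds (default 10, stratified).
#' @param lambda_rule `"min"` (minimum CV deviance, default) or `"1se"`.
#' @param lambda optional fixed penalty overriding the cross-validated
#'   rule (the CV curve is still computed and stored).
#' @param seed RNG seed controlling folds and RFE permutations.
#' @param cost,gamma RBF-SVM hyperparameters passed to [svm_rfe_rank()].
#' @param rfe_step elimination fraction per RFE round.
#' @return An object of class `radiomic_signature`: intercept, named
#'   non-zero `coefficients` (on the z-score scale), `normalization`
#'   parameters for the signature features, cross-validation curve, RFE
#'   ranking, and `provenance = "fitted"`.
#' @seealso [published_signature()], [radiomics_score()],
#'   [predict.radiomic_signature()]
#' @export
radiomic_signature <- function(x, y, variance_threshold = 0, rfe = TRUE,
                               rfe_k = 30, nfolds = 10,
                               lambda_rule = c("min", "1se"), seed = 1,
                               cost = 0.78, gamma = 0.00069,
                               rfe_step = 0.1, lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as_feature_matrix(x)
  y <- if (is.factor(y)) as.integer(y) - 1L else as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(unique(y)) < 2) stop("both classes must be present")
  keep <- variance_filter(x, variance_threshold)
  norm_all <- zscore_fit(x[, keep, drop = FALSE])
  z <- zscore_apply(x, norm_all)
  rfe_result <- NULL
  if (isTRUE(rfe) && rfe_k < ncol(z)) {
    rfe_result <- svm_rfe_rank(z, y, target_k = rfe_k,
                               step_fraction = rfe_step, cost = cost,
                               gamma = gamma, seed = seed)
    z <- z[, rfe_result$selected, drop = FALSE]
  }
  foldid <- with_seed(seed, stratified_folds(y, nfolds))
  # glmnet needs >= 2 columns; pad a constant (never-selected) dummy
  padded <- ncol(z) == 1L
  zfit <- if (padded) cbind(z, `..pad..` = 0) else z
  cv <- glmnet::cv.glmnet(zfit, y, family = "binomial", foldid = foldid,
                          type.measure = "deviance", standardize = FALSE,
                          thresh = 1e-7)
  if (is.null(lambda))
    lambda <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.matrix(coef(cv, s = lambda))[, 1]
  beta <- cf[-1][cf[-1] != 0]
  beta <- beta[names(beta) != "..pad.."]
  sel <- names(beta)
  structure(list(
    intercept = unname(cf[1]),
    coefficients = beta,
    normalization = list(mean = norm_all$mean[sel], sd = norm_all$sd[sel]),
    provenance = "fitted",
    lambda = lambda,
    lambda_rule = lambda_rule,
    cv = list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
              nzero = as.integer(cv$nzero), lambda_min = cv$lambda.min,
              lambda_1se = cv$lambda.1se),
    retained = keep,
    rfe = rfe_result,
    nfolds = nfolds,
    seed = seed), class = "radiomic_signature")
}

#' The published five-feature radiomics signature
#'
#' The reported CT radiomics score for discriminating TNBC from NTNBC:
#' `score = -2.21 + 0.03 * compactness - 55.21 * GLZM + 0.18 * GLSZM +
#' 0.36 * band-max + 1.69 * band-mean`. The model is evaluated on feature
#' maps that provide exactly these five names; no normalization is
#' attached.
#'
#' @return An object of class `radiomic_signature` with
#'   `provenance = "published"`.
#' @export
published_signature <- function() {
  structure(list(
    intercept = -2.21,
    coefficients = c(compactness = 0.03, GLZM = -55.21, GLSZM = 0.18,
                     `band-max` = 0.36, `band-mean` = 1.69),
    normalization = NULL,
    provenance = "published"), class = "radiomic_signature")
}

#' Compute radiomics scores
#'
#' The linear score `intercept + sum(coefficient * feature)`. Fitted
#' signatures first apply their stored z-score normalization; the published
#' signature is evaluated on the raw named values. Every feature named by
#' the model must be present.
#'
#' @param model a `radiomic_signature`.
#' @param features named numeric vector, or a matrix/data.frame with one
#'   row per patient and named columns.
#' @return numeric vector of scores.
#' @export
radiomics_score <- function(model, features) {
  stopifnot(inherits(model, "radiomic_signature"))
  if (is.null(dim(features))) features <- t(as.matrix(features))
  features <- as.matrix(features)
  need <- names(model$coefficients)
  miss <- setdiff(need, colnames(features))
  if (length(miss))
    stop("missing-feature error: ", paste(miss, collapse = ", "))
  v <- features[, need, drop = FALSE]
  if (!is.null(model$normalization))
    v <- sweep(sweep(v, 2, model$normalization$mean), 2,
               model$normalization$sd, `/`)
  unname(model$intercept + drop(v %*% model$coefficients))
}

#' Predict method for radiomics signatures
#'
#' @param object a `radiomic_signature`.
#' @param newdata named feature vector, matrix or data.frame (raw scale).
#' @param type `"score"` (linear radiomics score, default), `"prob"`
#'   (logistic probability of the positive class), or `"class"` (0/1 at
#'   `cutoff` on the score scale).
#' @param cutoff score cutoff for `type = "class"`.
#' @param ... unused.
#' @export
predict.radiomic_signature <- function(object, newdata,
                                       type = c("score", "prob", "class"),
                                       cutoff = 0, ...) {
  type <- match.arg(type)
  s <- radiomics_score(object, newdata)
  switch(type, score = s, prob = plogis(s),
         class = as.integer(s >= cutoff))
}

#' @export
coef.radiomic_signature <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.radiomic_signature <- function(x, ...) {
  cat("Radiomics signature (", x$provenance, "), ",
      length(x$coefficients), " features\n", sep = "")
  terms <- paste(sprintf("%+.4g * %s", x$coefficients,
                         names(x$coefficients)), collapse = " ")
  cat("  score =", sprintf("%.4g", x$intercept), terms, "\n")
  invisible(x)
}

#' @export
summary.radiomic_signature <- function(object, ...) {
  print(object)
  if (object$provenance == "fitted") {
    i <- which.min(abs(object$cv$lambda - object$lambda))
    cat(sprintf("  lambda = %.5g (%s rule), CV binomial deviance %.4f\n",
                object$lambda, object$lambda_rule, object$cv$cvm[i]))
    cat(sprintf("  %d features entered the LASSO; %d retained pre-LASSO\n",
                length(if (is.null(object$rfe)) object$retained
                       else object$rfe$selected),
                length(object$retained)))
  }
  invisible(object)
}

#' Plot the cross-validation curve of a fitted signature
#'
#' Mean cross-validated binomial deviance against log(lambda), with one
#' standard error bars and the selected lambda marked.
#'
#' @param x a fitted `radiomic_signature`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.radiomic_signature <- function(x, ...) {
  if (is.null(x$cv)) stop("no cross-validation curve: published signature")
  ll <- log(x$cv$lambda)
  graphics::plot(ll, x$cv$cvm, type = "b", pch = 20,
                 xlab = "log(lambda)", ylab = "CV binomial deviance", ...)
  graphics::arrows(ll, x$cv$cvm - x$cv$cvsd, ll, x$cv$cvm + x$cv$cvsd,
                   angle = 90, code = 3, length = 0.02, col = "grey60")
  graphics::abline(v = log(x$lambda), lty = 2)
  invisible(x)
}

#' Serialize / restore a signature as JSON
#'
#' Stores the evaluable part of the model (intercept, coefficients,
#' normalization, provenance, lambda); the cross-validation curve and RFE
#' audit trail are not round-tripped.
#'
#' @param model a `radiomic_signature`.
#' @param path JSON file path.
#' @return `path` / the restored `radiomic_signature`.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "radiomic_signature"))
  jsonlite::write_json(list(
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    normalization = if (is.null(model$normalization)) NULL else
      list(mean = as.list(model$normalization$mean),
           sd = as.list(model$normalization$sd)),
    provenance = model$provenance,
    lambda = model$lambda), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  j <- jsonlite::read_json(path)
  structure(list(
    intercept = j$intercept,
    coefficients = unlist(j$coefficients),
    normalization = if (length(j$normalization) == 0) NULL else
      list(mean = unlist(j$normalization$mean),
           sd = unlist(j$normalization$sd)),
    provenance = j$provenance,
    lambda = j$lambda %||% NULL), class = "radiomic_signature")
}
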