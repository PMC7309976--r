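# Diagnostic evaluation: ROC/AUC, optimal cutoff, predictive values with
# exact intervals, ICC for observer agreement, and baseline group
# comparisons.

check_binary_labels <- function(labels) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(unique(y)) < 2)
    stop("undefined-AUC error: both classes must be present")
  y
}

#' AUC with DeLong 95% confidence interval
#'
#' The area under the ROC curve computed by the rank (Mann-Whitney)
#' identity with midrank tie handling; the confidence interval uses the
#' DeLong variance estimate. Higher scores indicate the positive class.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive).
#' @return `list(auc, ci)` with `ci = c(lower, upper)`.
#' @export
roc_auc <- function(scores, labels) {
  y <- check_binary_labels(labels)
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # pROC warns that the DeLong interval of a degenerate AUC of exactly 1
  # collapses; the collapsed interval is still the correct report
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(
    pROC::roc(response = y, predictor = scores, levels = c(0, 1),
              direction = "<", quiet = TRUE), method = "delong")))[c(1, 3)]
  list(auc = auc, ci = ci)
}

#' ROC curve points
#'
#' Sensitivity/1-specificity pairs over all observed thresholds under the
#' rule score >= threshold => positive.
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  y <- check_binary_labels(labels)
  th <- c(sort(unique(scores)), Inf)
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[y == 0] >= t), 0),
    tpr = vapply(th, function(t) mean(scores[y == 1] >= t), 0))
}

#' Optimal score cutoff by the Youden index
#'
#' Maximizes J = sensitivity + specificity - 1 over the observed scores
#' under the rule score >= cutoff => positive. Ties are broken toward
#' higher specificity (and then the larger cutoff).
#'
#' @inheritParams roc_auc
#' @param rule only `"youden"` is implemented.
#' @return the cutoff (numeric scalar).
#' @export
optimal_cutoff <- function(scores, labels, rule = "youden") {
  stopifnot(rule == "youden")
  y <- check_binary_labels(labels)
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(c) mean(scores[y == 1] >= c), 0)
  spec <- vapply(cand, function(c) mean(scores[y == 0] < c), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[spec[best] == max(spec[best])]
  cand[max(best)]
}

clopper_pearson <- function(x, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(binom.test(x, n)$conf.int)
}

#' Full diagnostic report at a cutoff
#'
#' Confusion-table metrics under score >= cutoff => positive: sensitivity,
#' specificity, PPV, NPV and accuracy with Clopper-Pearson 95% intervals,
#' plus the AUC with its DeLong interval.
#'
#' @inheritParams roc_auc
#' @param cutoff score cutoff; when `NULL`, the Youden-optimal cutoff of
#'   this data is used.
#' @param cohort optional cohort name carried in the report.
#' @return object of class `diagnostic_report`.
#' @export
diagnostic_report <- function(scores, labels, cutoff = NULL, cohort = "") {
  y <- check_binary_labels(labels)
  if (is.null(cutoff)) cutoff <- optimal_cutoff(scores, labels)
  pos <- scores >= cutoff
  tp <- sum(pos & y == 1); fn <- sum(!pos & y == 1)
  fp <- sum(pos & y == 0); tn <- sum(!pos & y == 0)
  met <- function(x, n) list(estimate = if (n > 0) x / n else NA_real_,
                             ci = clopper_pearson(x, n))
  a <- roc_auc(scores, labels)
  structure(list(
    cohort = cohort, cutoff = cutoff,
    auc = a$auc, auc_ci95 = a$ci,
    sensitivity = met(tp, tp + fn),
    specificity = met(tn, tn + fp),
    ppv = met(tp, tp + fp),
    npv = met(tn, tn + fn),
    accuracy = met(tp + tn, length(y)),
    n_pos = sum(y == 1), n_neg = sum(y == 0),
    confusion = c(tp = tp, fp = fp, fn = fn, tn = tn)),
    class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Diagnostic report", if (nzchar(x$cohort)) paste0("(", x$cohort, ")"),
      "\n")
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), cutoff %.4g\n", x$auc,
              x$auc_ci95[1], x$auc_ci95[2], x$cutoff))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    cat(sprintf("  %-12s %.3f (%.3f-%.3f)\n", m, x[[m]]$estimate,
                x[[m]]$ci[1], x[[m]]$ci[2]))
  cat(sprintf("  n = %d positive / %d negative\n", x$n_pos, x$n_neg))
  invisible(x)
}

report_to_list <- function(x) {
  list(cohort = x$cohort, cutoff = x$cutoff, auc = x$auc,
       auc_ci95 = x$auc_ci95,
       sensitivity = x$sensitivity, specificity = x$specificity,
       ppv = x$ppv, npv = x$npv, accuracy = x$accuracy,
       n_pos = x$n_pos, n_neg = x$n_neg, confusion = as.list(x$confusion))
}

#' Intraclass correlation coefficient
#'
#' Single-measurement ICC from the two-way ANOVA decomposition of a
#' subjects x raters matrix. The default `"icc2_1"` is the two-way
#' random-effects absolute-agreement form; `"icc3_1"` is the two-way mixed
#' consistency form. 95% confidence intervals use the F-based formulas
#' (McGraw & Wong). Reliability is flagged as good when ICC > 0.75.
#'
#' @param measurements numeric matrix, subjects in rows, raters in columns,
#'   no missing cells.
#' @param form `"icc2_1"` (default) or `"icc3_1"`.
#' @param conf confidence level (default 0.95).
#' @return object of class `icc_result`: `icc`, `form`, `ci95`,
#'   `n_subjects`, `n_raters`, `reliable`.
#' @export
icc <- function(measurements, form = c("icc2_1", "icc3_1"), conf = 0.95) {
  form <- match.arg(form)
  m <- as.matrix(measurements)
  if (any(!is.finite(m))) stop("missing or non-finite cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  grand <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf
  if (ssr <= 1e-12 * max(sst, 1)) {
    warning("zero between-subject variance; ICC set to 0")
    val <- 0; ci <- c(NA_real_, NA_real_)
  } else if (form == "icc3_1") {
    val <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    fl <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    a <- k * val / (n * (1 - val))
    b <- 1 + k * val * (n - 1) / (n * (1 - val))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    ci <- c(n * (msr - fl * mse) /
              (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
            n * (fu * msr - mse) /
              (k * msc + (k * n - k - n) * mse + n * fu * msr))
  }
  structure(list(icc = val, form = form, ci95 = ci, n_subjects = n,
                 n_raters = k, reliable = is.finite(val) && val > 0.75),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s) = %.3f (95%% CI %.3f-%.3f), %d subjects x %d raters; %s\n",
              x$form, x$icc, x$ci95[1], x$ci95[2], x$n_subjects, x$n_raters,
              if (isTRUE(x$reliable)) "good reliability (> 0.75)"
              else "below the 0.75 reliability rule"))
  invisible(x)
}

#' Two-group comparison for baseline tables
#'
#' Chi-square (Pearson, no continuity correction) for categorical
#' variables, Welch t-test for normal continuous variables, Mann-Whitney U
#' otherwise (exact p for small untied samples, normal approximation with
#' tie correction otherwise, as in [stats::wilcox.test()]).
#'
#' @param values the variable (numeric, or factor/character for
#'   categorical).
#' @param group grouping factor with at least 2 levels.
#' @param type `"categorical"`, `"continuous-normal"` or
#'   `"continuous-nonnormal"`.
#' @param variable optional variable name carried in the result.
#' @return object of class `group_comparison`: test used, statistic,
#'   p-value, per-group summaries.
#' @export
compare_groups <- function(values, group,
                           type = c("categorical", "continuous-normal",
                                    "continuous-nonnormal"),
                           variable = deparse(substitute(values))) {
  type <- match.arg(type)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need at least 2 groups")
  if (type == "categorical") {
    tab <- table(group, values)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(dim(tab) < 2) || any(exp_counts == 0))
      stop("test-inapplicable error: expected cell count 0 ",
           "(a group or category is empty)")
    tst <- suppressWarnings(chisq.test(tab, correct = FALSE))
    summaries <- as.data.frame.matrix(tab)
    out <- list(test = "chi-square", statistic = unname(tst$statistic),
                p_value = tst$p.value)
  } else if (type == "continuous-normal") {
    tst <- t.test(values ~ group)
    summaries <- do.call(rbind, tapply(values, group, function(v)
      data.frame(n = length(v), mean = mean(v), sd = sd(v))))
    out <- list(test = "t", statistic = unname(tst$statistic),
                p_value = tst$p.value)
  } else {
    tst <- wilcox.test(values ~ group)
    summaries <- do.call(rbind, tapply(values, group, function(v)
      data.frame(n = length(v), median = median(v),
                 q1 = unname(quantile(v, 0.25)),
                 q3 = unname(quantile(v, 0.75)))))
    out <- list(test = "mann-whitney", statistic = unname(tst$statistic),
                p_value = tst$p.value)
  }
  structure(c(list(variable = variable), out, list(summaries = summaries)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s test, statistic = %.4g, p = %.4g\n", x$variable,
              x$test, x$statistic, x$p_value))
  print(x$summaries)
  invisible(x)
}

#' Baseline comparison table
#'
#' Applies [compare_groups()] to several variables at once, in the style of
#' a clinical baseline table.
#'
#' @param data data.frame holding the variables and the grouping column.
#' @param group name of the grouping column.
#' @param vars character vector of variable names.
#' @param types per-variable types, recycled (see [compare_groups()]).
#' @return data.frame with one row per variable: test, statistic, p-value.
#' @export
baseline_table <- function(data, group, vars,
                           types = "continuous-nonnormal") {
  types <- rep_len(types, length(vars))
  rows <- lapply(seq_along(vars), function(i) {
    cmp <- compare_groups(data[[vars[i]]], data[[group]], types[i],
                          variable = vars[i])
    data.frame(variable = vars[i], test = cmp$test,
               statistic = cmp$statistic, p_value = cmp$p_value)
  })
  do.call(rbind, rows)
}
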