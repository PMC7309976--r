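# ROC/AUC, cutoffs, diagnostic reports, ICC and group comparisons.

test_that("AUC hits the separation limit and the rank identity", {
  scores <- c(0.1, 0.2, 0.8, 0.9)
  labels <- c(0, 0, 1, 1)
  expect_equal(roc_auc(scores, labels)$auc, 1)
  # rank identity against an independently computed Mann-Whitney U
  set.seed(44)
  for (rep in 1:10) {
    n1 <- sample(10:40, 1); n0 <- sample(10:40, 1)
    s <- c(rnorm(n0), rnorm(n1, 0.6))
    # ties on purpose in half the cases
    if (rep %% 2 == 0) s <- round(s, 1)
    y <- rep(c(0, 1), c(n0, n1))
    u <- 0
    for (i in which(y == 1)) for (j in which(y == 0))
      u <- u + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    expect_equal(roc_auc(s, y)$auc, u / (n1 * n0), tolerance = 1e-12)
  }
  expect_error(roc_auc(scores, c(1, 1, 1, 1)), "undefined-AUC")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(15)
  s <- rnorm(80); y <- rbinom(80, 1, plogis(s))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(s), y)$auc, a, tolerance = 1e-12)
})

test_that("null scores give AUC near one half with a covering DeLong CI", {
  set.seed(16)
  aucs <- replicate(60, {
    s <- rnorm(200); y <- rep(c(0, 1), each = 100)
    roc_auc(s, y)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  r <- roc_auc(rnorm(200), rep(c(0, 1), each = 100))
  expect_lte(r$ci[1], r$auc); expect_gte(r$ci[2], r$auc)
})

test_that("Youden cutoff matches an exhaustive scan and breaks ties to specificity", {
  set.seed(17)
  for (rep in 1:12) {
    s <- round(rnorm(50), 1)
    y <- rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    cut <- optimal_cutoff(s, y)
    j_at <- function(c) mean(s[y == 1] >= c) + mean(s[y == 0] < c) - 1
    jall <- vapply(sort(unique(s)), j_at, 0)
    expect_equal(j_at(cut), max(jall), tolerance = 1e-12)
  }
  # separable toy: any cutoff in (0.2, 0.8] is optimal; ties resolve to the
  # most specific (largest) candidate
  cut <- optimal_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(cut, 0.8)
})

test_that("diagnostic reports satisfy the confusion-table identities", {
  set.seed(18)
  s <- rnorm(120); y <- rbinom(120, 1, plogis(2 * s))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  rep_ <- diagnostic_report(s, y, cohort = "toy")
  cm <- rep_$confusion
  expect_equal(rep_$sensitivity$estimate, cm["tp"] / (cm["tp"] + cm["fn"]),
               ignore_attr = TRUE)
  expect_equal(rep_$specificity$estimate, cm["tn"] / (cm["tn"] + cm["fp"]),
               ignore_attr = TRUE)
  expect_equal(rep_$accuracy$estimate,
               (cm["tp"] + cm["tn"]) / sum(cm), ignore_attr = TRUE)
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    expect_gte(rep_[[m]]$estimate, rep_[[m]]$ci[1])
    expect_lte(rep_[[m]]$estimate, rep_[[m]]$ci[2])
  }
  # degenerate cutoff below the minimum: everything called positive
  rlow <- diagnostic_report(s, y, cutoff = min(s) - 1)
  expect_equal(rlow$sensitivity$estimate, 1)
  expect_equal(rlow$specificity$estimate, 0)
  expect_equal(rlow$ppv$estimate, mean(y))
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  set.seed(19)
  for (p in c(0.1, 0.5, 0.9)) {
    hits <- replicate(1000, {
      x <- rbinom(1, 40, p)
      ci <- binom.test(x, 40)$conf.int
      ci[1] <= p && p <= ci[2]
    })
    expect_gte(mean(hits), 0.95 - 0.02)
  }
})

test_that("ICC limits: perfect agreement and noise-dominated raters", {
  set.seed(20)
  base <- rnorm(100, 50, 5)
  m_same <- cbind(base, base)
  expect_equal(icc(m_same)$icc, 1, tolerance = 1e-12)
  # rater 2 noise sd 10x the subject sd: true ICC ~ 0.01; median estimate
  # over replicates stays below 0.05
  noisy <- replicate(15, {
    b <- rnorm(100, 50, 5)
    icc(cbind(b, b + rnorm(100, 0, 50)))$icc
  })
  expect_lt(median(noisy), 0.05)
  # degenerate: no between-subject variance
  expect_warning(z <- icc(matrix(5, 10, 2)), "between-subject")
  expect_equal(z$icc, 0)
})

test_that("consistency ICC ignores a rater offset, agreement ICC does not", {
  set.seed(22)
  base <- rnorm(60, 0, 2)
  m <- cbind(base + rnorm(60, 0, 0.5), base + rnorm(60, 0, 0.5))
  shifted <- m; shifted[, 2] <- shifted[, 2] + 3
  expect_equal(icc(shifted, form = "icc3_1")$icc, icc(m, form = "icc3_1")$icc,
               tolerance = 1e-10)
  expect_lt(icc(shifted, form = "icc2_1")$icc, icc(m, form = "icc2_1")$icc)
})

test_that("ICC(2,1) recovers the variance-ratio truth on simulated data", {
  set.seed(23)
  k <- 2
  for (true_icc in c(0.3, 0.8)) {
    sig_s <- sqrt(true_icc); sig_e <- sqrt(1 - true_icc)
    est <- replicate(25, {
      subj <- rnorm(200, 0, sig_s)
      m <- sapply(1:k, function(j) subj + rnorm(200, 0, sig_e))
      icc(m)$icc
    })
    expect_lt(abs(median(est) - true_icc), 0.05)
  }
})

test_that("group comparisons: hand-computed chi-square and exact Mann-Whitney", {
  g <- rep(c("a", "b"), each = 10)
  v <- rep(c("x", "y"), each = 10)  # perfectly associated 2x2: [[10,0],[0,10]]
  cmp <- compare_groups(v, g, "categorical")
  expect_equal(cmp$statistic, 20)
  expect_identical(cmp$test, "chi-square")
  # exact Mann-Whitney on {1,2,3} vs {4,5,6}
  cmp2 <- compare_groups(c(1, 2, 3, 4, 5, 6),
                         rep(c("a", "b"), each = 3),
                         "continuous-nonnormal")
  expect_equal(unname(cmp2$statistic), 0)
  expect_equal(cmp2$p_value, 0.1)
  # identical distributions: statistic near zero for t-test
  set.seed(25)
  v3 <- rnorm(200)
  cmp3 <- compare_groups(v3, rep(c("a", "b"), 100), "continuous-normal")
  expect_gt(cmp3$p_value, 0.01)
  # inapplicable when a category is absent in expectation
  expect_error(compare_groups(rep("x", 20), g, "categorical"),
               "test-inapplicable")
})

test_that("baseline_table runs several variables at once", {
  set.seed(26)
  df <- data.frame(grp = rep(c("discovery", "validation"), each = 40),
                   age = rnorm(80, 50, 10),
                   stage = sample(c("I", "II", "III"), 80, replace = TRUE))
  tb <- baseline_table(df, "grp", c("age", "stage"),
                       c("continuous-normal", "categorical"))
  expect_identical(nrow(tb), 2L)
  expect_true(all(tb$p_value >= 0 & tb$p_value <= 1))
})
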