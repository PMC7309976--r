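# The radiomics signature: published model, linear scoring, LASSO fit and
# its S3 interface.

test_that("the published signature has the printed intercept and 5 coefficients", {
  m <- published_signature()
  expect_identical(length(m$coefficients), 5L)
  expect_identical(unname(sign(m$coefficients)), c(1, -1, 1, 1, 1))
  zero <- setNames(rep(0, 5), names(m$coefficients))
  expect_identical(radiomics_score(m, zero), -2.21)
  # raising band-mean by 1 raises the score by its coefficient, 1.69
  up <- zero; up["band-mean"] <- 1
  expect_equal(radiomics_score(m, up) - radiomics_score(m, zero), 1.69)
  expect_error(radiomics_score(m, zero[-1]), "missing-feature")
})

test_that("scores are linear in each feature", {
  m <- published_signature()
  set.seed(8)
  base <- setNames(rnorm(5), names(m$coefficients))
  s0 <- radiomics_score(m, base)
  for (f in names(m$coefficients)) {
    delta <- runif(1, 0.5, 2)
    shifted <- base; shifted[f] <- shifted[f] + delta
    expect_equal(radiomics_score(m, shifted) - s0,
                 unname(m$coefficients[f]) * delta, tolerance = 1e-12)
  }
  # degenerate model: intercept only
  m0 <- structure(list(intercept = 1.5, coefficients = setNames(numeric(0),
                                                                character(0)),
                       normalization = NULL, provenance = "published"),
                  class = "radiomic_signature")
  expect_equal(radiomics_score(m0, base), 1.5)
})

test_that("signature JSON serialization round-trips", {
  m <- published_signature()
  f <- tempfile(fileext = ".json")
  write_signature(m, f)
  back <- read_signature(f)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coefficients, m$coefficients)
  expect_identical(back$provenance, "published")
  x <- setNames(rnorm(5), names(m$coefficients))
  expect_equal(radiomics_score(back, x), radiomics_score(m, x))
})

simulate_logistic <- function(n, p, beta, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  eta <- drop(x[, seq_along(beta), drop = FALSE] %*% beta)
  y <- rbinom(n, 1, plogis(eta))
  list(x = x, y = y)
}

test_that("full shrinkage yields an intercept-only model at prevalence", {
  sim <- simulate_logistic(150, 8, c(1, -1), seed = 4)
  fit <- radiomic_signature(sim$x, sim$y, rfe = FALSE, seed = 2,
                            lambda = 50)
  expect_identical(length(fit$coefficients), 0L)
  expect_equal(plogis(fit$intercept), mean(sim$y), tolerance = 1e-6)
  expect_equal(predict(fit, sim$x), rep(fit$intercept, 150))
})

test_that("LASSO recovers a planted 5-of-30 support (median over seeds)", {
  recovered <- vapply(1:20, function(s) {
    sim <- simulate_logistic(200, 30, c(1, -1, 1, -1, 1), seed = 100 + s)
    z <- zscore_apply(sim$x, zscore_fit(sim$x))
    fit <- radiomic_signature(z, sim$y, rfe = FALSE, seed = s)
    sum(paste0("f", 1:5) %in% names(fit$coefficients))
  }, 0)
  expect_gte(median(recovered), 4)
  # support Jaccard with the truth, under the sparser one-SE lambda rule
  jac <- vapply(1:10, function(s) {
    sim <- simulate_logistic(200, 30, c(1, -1, 1, -1, 1), seed = 100 + s)
    fit <- radiomic_signature(sim$x, sim$y, rfe = FALSE, seed = s,
                              lambda_rule = "1se")
    sel <- names(fit$coefficients)
    length(intersect(sel, paste0("f", 1:5))) /
      length(union(sel, paste0("f", 1:5)))
  }, 0)
  expect_gte(median(jac), 0.6)
})

test_that("nonzero-coefficient count is monotone along the lambda grid", {
  sim <- simulate_logistic(200, 12, c(1.5, -1.5, 1), seed = 6)
  fit <- radiomic_signature(sim$x, sim$y, rfe = FALSE, seed = 1)
  nz <- fit$cv$nzero  # ordered by decreasing lambda
  expect_true(all(diff(nz) >= 0))
})

test_that("separable single feature keeps a finite positive coefficient", {
  x <- matrix(c(rnorm(50, -3), rnorm(50, 3)), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- rep(c(0, 1), each = 50)
  fit <- suppressWarnings(radiomic_signature(x, y, rfe = FALSE, nfolds = 5,
                                             seed = 3))
  expect_true(is.finite(fit$coefficients["f1"]))
  expect_gt(fit$coefficients["f1"], 0)
})

test_that("fit is invariant to affine rescaling of raw features", {
  sim <- simulate_logistic(150, 10, c(1, -1, 1), seed = 12)
  fit1 <- radiomic_signature(sim$x, sim$y, rfe = FALSE, seed = 5)
  x2 <- sweep(sweep(sim$x, 2, seq(2, 20, by = 2), `*`), 2, rnorm(10), `+`)
  fit2 <- radiomic_signature(x2, sim$y, rfe = FALSE, seed = 5)
  expect_identical(names(fit1$coefficients), names(fit2$coefficients))
  s1 <- predict(fit1, sim$x); s2 <- predict(fit2, x2)
  expect_equal(order(s1), order(s2))
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("the S3 surface behaves: print, coef, summary, predict, plot", {
  sim <- simulate_logistic(120, 6, c(2, -2), seed = 33)
  fit <- radiomic_signature(sim$x, sim$y, rfe = FALSE, nfolds = 5, seed = 1)
  expect_s3_class(fit, "radiomic_signature")
  expect_output(print(fit), "Radiomics signature")
  expect_output(summary(fit), "lambda")
  cf <- coef(fit)
  expect_identical(names(cf)[1], "(Intercept)")
  pr <- predict(fit, sim$x, type = "prob")
  expect_true(all(pr >= 0 & pr <= 1))
  cl <- predict(fit, sim$x, type = "class", cutoff = 0)
  expect_true(all(cl %in% c(0L, 1L)))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
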