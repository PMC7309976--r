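#' First-order intensity statistics of a VOI
#'
#' The 18 first-order features: energy, histogram entropy (bits, over the
#' discretized grey levels), minimum, maximum, mean, median, mean absolute
#' deviation about the mean, root-mean-square, standard deviation, skewness,
#' kurtosis (non-excess; a Gaussian scores 3), variance, uniformity, and the
#' percentile statistics p10, p90, interquartile range, range, and robust
#' mean absolute deviation (over values within the 10th-90th percentile
#' band). Moments use population (n) denominators. A constant VOI has
#' entropy 0, uniformity 1, and skewness/kurtosis 0 by the 0/0 convention.
#'
#' @param voi a [make_voi()] object.
#' @return named numeric vector of length 18 (names `firstorder.*`).
#' @export
firstorder_features <- function(voi) {
  x <- voi$values
  n <- length(x)
  if (n == 0) stop("empty-VOI error")
  lev <- voi$levels[voi$mask]
  p <- tabulate(lev, nbins = voi$n_levels) / n
  p <- p[p > 0]
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- sqrt(v)
  q <- unname(quantile(x, c(0.1, 0.25, 0.75, 0.9)))
  band <- x[x >= q[1] & x <= q[4]]
  out <- c(
    energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    minimum = min(x),
    maximum = max(x),
    mean = m,
    median = median(x),
    mad = mean(abs(x - m)),
    rms = sqrt(mean(x^2)),
    sd = s,
    skewness = if (s > 0) mean((x - m)^3) / s^3 else 0,
    kurtosis = if (s > 0) mean((x - m)^4) / v^2 else 0,
    variance = v,
    uniformity = sum(p^2),
    p10 = q[1],
    p90 = q[4],
    iqr = q[3] - q[2],
    range = max(x) - min(x),
    robust_mad = mean(abs(band - mean(band))))
  names(out) <- paste0("firstorder.", FIRSTORDER_NAMES)
  out
}
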