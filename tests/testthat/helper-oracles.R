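# Independent brute-force oracles: naive enumeration of voxel pairs, runs,
# zones and neighbourhoods with explicit loops, kept deliberately separate
# from the package implementation.

oracle_offsets <- function() {
  o <- NULL
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    v <- c(dx, dy, dz)
    if (all(v == 0)) next
    if (is.null(o) || !any(apply(o, 1, function(r) all(r == -v))))
      o <- rbind(o, v)
  }
  o  # 13 unique direction representatives
}

at <- function(lv, p) {
  d <- dim(lv)
  if (any(p < 1) || any(p > d)) return(0L)
  lv[p[1], p[2], p[3]]
}

# ---- GLCM ---------------------------------------------------------------

oracle_glcm_avg <- function(lv, ng, distance = 1) {
  offs <- oracle_offsets() * distance
  d <- dim(lv)
  mats <- list()
  for (k in seq_len(nrow(offs))) {
    C <- matrix(0, ng, ng)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lv[x, y, z]
      if (a == 0) next
      b <- at(lv, c(x, y, z) + offs[k, ])
      if (b == 0) next
      C[a, b] <- C[a, b] + 1
      C[b, a] <- C[b, a] + 1
    }
    if (sum(C) > 0) mats[[length(mats) + 1]] <- C / sum(C)
  }
  if (length(mats) == 0) {
    P <- matrix(0, ng, ng)
    l1 <- lv[lv > 0][1]
    P[l1, l1] <- 1
    return(P)
  }
  Reduce(`+`, mats) / length(mats)
}

oracle_glcm_features <- function(lv, ng, distance = 1) {
  P <- oracle_glcm_avg(lv, ng, distance)
  px <- rowSums(P)
  mu <- 0; for (i in 1:ng) for (j in 1:ng) mu <- mu + i * P[i, j]
  sig2 <- 0; for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu)^2 * P[i, j]
  psum <- rep(0, 2 * ng - 1); pdif <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j - 1] <- psum[i + j - 1] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  acc <- function(f) { s <- 0
    for (i in 1:ng) for (j in 1:ng) s <- s + f(i, j, P[i, j]); s }
  da <- sum((0:(ng - 1)) * pdif)
  sa <- sum((2:(2 * ng)) * psum)
  hxy <- ent(P); hx <- ent(px)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * px[j]
    if (q > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  c(autocorrelation = acc(function(i, j, p) i * j * p),
    joint_average = mu,
    cluster_prominence = acc(function(i, j, p) (i + j - 2 * mu)^4 * p),
    cluster_shade = acc(function(i, j, p) (i + j - 2 * mu)^3 * p),
    cluster_tendency = acc(function(i, j, p) (i + j - 2 * mu)^2 * p),
    contrast = acc(function(i, j, p) (i - j)^2 * p),
    correlation = if (sig2 > 0)
      (acc(function(i, j, p) i * j * p) - mu^2) / sig2 else 1,
    difference_average = da,
    difference_entropy = ent(pdif),
    difference_variance = sum(((0:(ng - 1)) - da)^2 * pdif),
    dissimilarity = acc(function(i, j, p) abs(i - j) * p),
    joint_energy = acc(function(i, j, p) p^2),
    joint_entropy = hxy,
    imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    idm = acc(function(i, j, p) p / (1 + (i - j)^2)),
    idmn = acc(function(i, j, p) p / (1 + ((i - j) / ng)^2)),
    id = acc(function(i, j, p) p / (1 + abs(i - j))),
    idn = acc(function(i, j, p) p / (1 + abs(i - j) / ng)),
    inverse_variance = acc(function(i, j, p) if (i != j) p / (i - j)^2 else 0),
    maximum_probability = max(P),
    sum_average = sa,
    sum_entropy = ent(psum),
    sum_squares = acc(function(i, j, p) (i - mu)^2 * p),
    sum_variance = sum(((2:(2 * ng)) - sa)^2 * psum))
}

# ---- GLRLM --------------------------------------------------------------

oracle_runs <- function(lv, ng) {
  offs <- oracle_offsets()
  d <- dim(lv)
  maxlen <- max(d)
  R <- matrix(0, ng, maxlen)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lv[x, y, z]
      if (a == 0) next
      if (at(lv, c(x, y, z) - o) == a) next  # not a run start
      len <- 1
      p <- c(x, y, z) + o
      while (at(lv, p) == a) { len <- len + 1; p <- p + o }
      R[a, len] <- R[a, len] + 1
    }
  }
  R
}

oracle_glrlm_features <- function(lv, ng) {
  R <- oracle_runs(lv, ng)
  nr <- sum(R); np <- 0
  for (g in seq_len(nrow(R))) for (r in seq_len(ncol(R)))
    np <- np + r * R[g, r]
  s <- function(f) { v <- 0
    for (g in seq_len(nrow(R))) for (r in seq_len(ncol(R)))
      v <- v + f(g, r, R[g, r]); v }
  p <- R / nr
  mug <- s(function(g, r, c) g * c / nr)
  mur <- s(function(g, r, c) r * c / nr)
  pp <- p[p > 0]
  c(sre = s(function(g, r, c) c / r^2) / nr,
    lre = s(function(g, r, c) c * r^2) / nr,
    gln = sum(rowSums(R)^2) / nr,
    glnn = sum(rowSums(R)^2) / nr^2,
    rln = sum(colSums(R)^2) / nr,
    rlnn = sum(colSums(R)^2) / nr^2,
    run_percentage = nr / np,
    gl_variance = s(function(g, r, c) (g - mug)^2 * c / nr),
    run_variance = s(function(g, r, c) (r - mur)^2 * c / nr),
    run_entropy = -sum(pp * log2(pp)),
    lgre = s(function(g, r, c) c / g^2) / nr,
    hgre = s(function(g, r, c) c * g^2) / nr,
    srlge = s(function(g, r, c) c / (g^2 * r^2)) / nr,
    srhge = s(function(g, r, c) c * g^2 / r^2) / nr,
    lrlge = s(function(g, r, c) c * r^2 / g^2) / nr,
    lrhge = s(function(g, r, c) c * g^2 * r^2) / nr)
}

# ---- GLSZM --------------------------------------------------------------

oracle_zones <- function(lv) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  zones <- NULL
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || lv[x, y, z] == 0) next
    lev <- lv[x, y, z]
    queue <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (any(q < 1) || any(q > d)) next
        if (!seen[q[1], q[2], q[3]] && lv[q[1], q[2], q[3]] == lev) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones <- rbind(zones, c(lev, size))
  }
  zones
}

oracle_glszm_features <- function(lv) {
  zn <- oracle_zones(lv)
  g <- zn[, 1]; s <- zn[, 2]
  nz <- nrow(zn); np <- sum(s)
  key <- paste(g, s)
  pcell <- as.numeric(table(key)) / nz
  c(sae = sum(1 / s^2) / nz,
    lae = sum(s^2) / nz,
    gln = sum(table(g)^2) / nz,
    glnn = sum(table(g)^2) / nz^2,
    szn = sum(table(s)^2) / nz,
    sznn = sum(table(s)^2) / nz^2,
    zone_percentage = nz / np,
    gl_variance = mean((g - mean(g))^2),
    zone_variance = mean((s - mean(s))^2),
    zone_entropy = -sum(pcell * log2(pcell)),
    lglze = sum(1 / g^2) / nz,
    hglze = sum(g^2) / nz,
    salge = sum(1 / (g^2 * s^2)) / nz,
    sahge = sum(g^2 / s^2) / nz,
    lalge = sum(s^2 / g^2) / nz,
    lahge = sum(g^2 * s^2) / nz)
}

# ---- NGTDM --------------------------------------------------------------

oracle_ngtdm_features <- function(lv, ng) {
  d <- dim(lv)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  s <- rep(0, ng); n <- rep(0, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    vals <- c()
    for (k in seq_len(nrow(nb))) {
      b <- at(lv, c(x, y, z) + nb[k, ])
      if (b > 0) vals <- c(vals, b)
    }
    if (length(vals)) {
      s[a] <- s[a] + abs(a - mean(vals))
      n[a] <- n[a] + 1
    }
  }
  ntot <- sum(n); p <- n / ntot
  pres <- which(n > 0); ngp <- length(pres)
  den <- sum(p * s)
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  for (i in pres) for (j in pres) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    complexity <- complexity +
      abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
    strength <- strength + (p[i] + p[j]) * (i - j)^2
  }
  c(coarseness = if (den > 1e-6) min(1 / den, 1e6) else 1e6,
    contrast = if (ngp > 1) contrast / (ngp * (ngp - 1)) * sum(s) / ntot else 0,
    busyness = if (busy_den > 0) den / busy_den else 0,
    complexity = complexity / ntot,
    strength = if (sum(s) > 0) strength / sum(s) else 0)
}

# ---- GLDM ---------------------------------------------------------------

oracle_gldm_features <- function(lv, ng, alpha = 0) {
  d <- dim(lv)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  P <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    dep <- 0
    for (k in seq_len(nrow(nb))) {
      b <- at(lv, c(x, y, z) + nb[k, ])
      if (b > 0 && abs(b - a) <= alpha) dep <- dep + 1
    }
    P[a, dep + 1] <- P[a, dep + 1] + 1
  }
  nz <- sum(P)
  sfun <- function(f) { v <- 0
    for (g in seq_len(nrow(P))) for (k in seq_len(ncol(P)))
      v <- v + f(g, k, P[g, k]); v }
  p <- P / nz
  mug <- sfun(function(g, k, c) g * c / nz)
  muk <- sfun(function(g, k, c) k * c / nz)
  pp <- p[p > 0]
  c(sde = sfun(function(g, k, c) c / k^2) / nz,
    lde = sfun(function(g, k, c) c * k^2) / nz,
    gln = sum(rowSums(P)^2) / nz,
    dn = sum(colSums(P)^2) / nz,
    dnn = sum(colSums(P)^2) / nz^2,
    gl_variance = sfun(function(g, k, c) (g - mug)^2 * c / nz),
    dependence_variance = sfun(function(g, k, c) (k - muk)^2 * c / nz),
    dependence_entropy = -sum(pp * log2(pp)),
    lgle = sfun(function(g, k, c) c / g^2) / nz,
    hgle = sfun(function(g, k, c) c * g^2) / nz,
    sdlge = sfun(function(g, k, c) c / (g^2 * k^2)) / nz,
    sdhge = sfun(function(g, k, c) c * g^2 / k^2) / nz,
    ldlge = sfun(function(g, k, c) c * k^2 / g^2) / nz,
    ldhge = sfun(function(g, k, c) c * g^2 * k^2) / nz)
}

# ---- first order --------------------------------------------------------

oracle_firstorder <- function(values, levels, ng) {
  n <- length(values)
  m <- sum(values) / n
  v <- sum((values - m)^2) / n
  s <- sqrt(v)
  cnt <- rep(0, ng)
  for (l in levels) cnt[l] <- cnt[l] + 1
  p <- cnt[cnt > 0] / n
  q <- unname(quantile(values, c(0.1, 0.25, 0.75, 0.9)))
  band <- values[values >= q[1] & values <= q[4]]
  c(energy = sum(values^2),
    entropy = -sum(p * log2(p)),
    minimum = min(values), maximum = max(values), mean = m,
    median = median(values),
    mad = sum(abs(values - m)) / n,
    rms = sqrt(sum(values^2) / n),
    sd = s,
    skewness = if (s > 0) sum((values - m)^3) / n / s^3 else 0,
    kurtosis = if (s > 0) sum((values - m)^4) / n / v^2 else 0,
    variance = v,
    uniformity = sum(p^2),
    p10 = q[1], p90 = q[4], iqr = q[3] - q[2],
    range = max(values) - min(values),
    robust_mad = mean(abs(band - mean(band))))
}
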