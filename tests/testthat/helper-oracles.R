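# Brute-force oracles: independent re-derivations of every texture-matrix
# family by explicit voxel/pair/run/zone/neighbour enumeration with plain
# loops, plus naive loop-based feature formulas. Deliberately slow and
# simple; they never share code with the package implementation.

o_dirs <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  g[g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
}

o_inside <- function(p, dm) all(p >= 1) && all(p <= dm)

# -- GLCM ---------------------------------------------------------------

o_glcm_matrix <- function(lev, ng, d) {
  dm <- dim(lev)
  C <- matrix(0, ng, ng)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (sgn in c(1, -1)) {
      q <- c(x, y, z) + sgn * d
      if (!o_inside(q, dm)) next
      b <- lev[q[1], q[2], q[3]]
      if (is.na(b)) next
      C[a, b] <- C[a, b] + 1
    }
  }
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

o_glcm_from_matrix <- function(P) {
  ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  ux <- 0; for (i in 1:ng) ux <- ux + i * px[i]
  uy <- 0; for (j in 1:ng) uy <- uy + j * py[j]
  sx2 <- 0; for (i in 1:ng) sx2 <- sx2 + px[i] * (i - ux)^2
  sy2 <- 0; for (j in 1:ng) sy2 <- sy2 + py[j] * (j - uy)^2

  psum <- rep(0, 2 * ng); pdif <- rep(0, ng)        # indices k and k+1
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pdif[k + 1]

  acc <- function(f) { s <- 0; for (i in 1:ng) for (j in 1:ng) s <- s + f(i, j); s }
  lg <- function(v) if (v > 0) log2(v) else 0
  hxy <- -acc(function(i, j) if (P[i, j] > 0) P[i, j] * lg(P[i, j]) else 0)
  hx <- 0; for (i in 1:ng) if (px[i] > 0) hx <- hx - px[i] * lg(px[i])
  hy <- 0; for (j in 1:ng) if (py[j] > 0) hy <- hy - py[j] * lg(py[j])
  hxy1 <- -acc(function(i, j) if (P[i, j] > 0) P[i, j] * lg(px[i] * py[j]) else 0)
  hxy2 <- -acc(function(i, j) if (px[i] * py[j] > 0)
    px[i] * py[j] * lg(px[i] * py[j]) else 0)

  de <- 0; for (k in 0:(ng - 1)) if (pdif[k + 1] > 0) de <- de - pdif[k + 1] * lg(pdif[k + 1])
  dv <- 0; for (k in 0:(ng - 1)) dv <- dv + (k - da)^2 * pdif[k + 1]
  sa <- 0; se <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * psum[k]
    if (psum[k] > 0) se <- se - psum[k] * lg(psum[k])
  }

  pos <- which(px > 0)
  mcc <- if (length(pos) < 2) 1 else {
    Q <- matrix(0, length(pos), length(pos))
    for (a in seq_along(pos)) for (b in seq_along(pos)) {
      s <- 0
      for (k in seq_along(pos))
        s <- s + P[pos[a], pos[k]] * P[pos[b], pos[k]] /
          (px[pos[a]] * py[pos[k]])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }

  c(Autocorrelation = acc(function(i, j) i * j * P[i, j]),
    ClusterProminence = acc(function(i, j) (i + j - ux - uy)^4 * P[i, j]),
    ClusterShade = acc(function(i, j) (i + j - ux - uy)^3 * P[i, j]),
    ClusterTendency = acc(function(i, j) (i + j - ux - uy)^2 * P[i, j]),
    Contrast = acc(function(i, j) (i - j)^2 * P[i, j]),
    Correlation = if (sx2 > 0 && sy2 > 0)
      (acc(function(i, j) i * j * P[i, j]) - ux * uy) / sqrt(sx2 * sy2) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = de,
    DifferenceVariance = dv,
    Id = acc(function(i, j) P[i, j] / (1 + abs(i - j))),
    Idm = acc(function(i, j) P[i, j] / (1 + (i - j)^2)),
    Idmn = acc(function(i, j) P[i, j] / (1 + (i - j)^2 / ng^2)),
    Idn = acc(function(i, j) P[i, j] / (1 + abs(i - j) / ng)),
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = acc(function(i, j) if (i != j) P[i, j] / (i - j)^2 else 0),
    JointAverage = ux,
    JointEnergy = acc(function(i, j) P[i, j]^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sa,
    SumEntropy = se,
    SumSquares = acc(function(i, j) (i - ux)^2 * P[i, j]))
}

o_glcm_features <- function(lev, ng) {
  ds <- o_dirs()
  acc <- NULL; nd <- 0
  for (k in seq_len(nrow(ds))) {
    P <- o_glcm_matrix(lev, ng, ds[k, ])
    if (is.null(P)) next
    f <- o_glcm_from_matrix(P)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  out <- acc / nd
  names(out) <- paste0("glcm_", names(out))
  out
}

# -- GLRLM --------------------------------------------------------------

o_glrlm_matrix <- function(lev, ng, d) {
  dm <- dim(lev)
  P <- matrix(0, ng, max(dm))
  flush <- function(cur, len) if (!is.na(cur) && len > 0) P[cur, len] <<- P[cur, len] + 1
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    if (o_inside(c(x, y, z) - d, dm)) next       # not a line start
    p <- c(x, y, z); cur <- NA; len <- 0
    while (o_inside(p, dm)) {
      v <- lev[p[1], p[2], p[3]]
      if (is.na(v)) { flush(cur, len); cur <- NA; len <- 0 }
      else if (!is.na(cur) && v == cur) len <- len + 1
      else { flush(cur, len); cur <- v; len <- 1 }
      p <- p + d
    }
    flush(cur, len)
  }
  P[, seq_len(max(1, max(which(colSums(P) > 0)))), drop = FALSE]
}

o_glrlm_from_matrix <- function(P, np) {
  ng <- nrow(P); nl <- ncol(P); N <- sum(P)
  gsum <- rowSums(P); lsum <- colSums(P)
  mu_g <- 0; for (i in 1:ng) mu_g <- mu_g + i * gsum[i] / N
  mu_l <- 0; for (l in 1:nl) mu_l <- mu_l + l * lsum[l] / N
  s <- function(f) { v <- 0; for (i in 1:ng) for (l in 1:nl) v <- v + f(i, l); v }
  re <- 0
  for (i in 1:ng) for (l in 1:nl) if (P[i, l] > 0)
    re <- re - P[i, l] / N * log2(P[i, l] / N)
  c(GrayLevelNonUniformity = sum(gsum^2) / N,
    GrayLevelNonUniformityNormalized = sum(gsum^2) / N^2,
    GrayLevelVariance = s(function(i, l) P[i, l] / N * (i - mu_g)^2),
    HighGrayLevelRunEmphasis = s(function(i, l) P[i, l] * i^2) / N,
    LongRunEmphasis = s(function(i, l) P[i, l] * l^2) / N,
    LongRunHighGrayLevelEmphasis = s(function(i, l) P[i, l] * i^2 * l^2) / N,
    LongRunLowGrayLevelEmphasis = s(function(i, l) P[i, l] * l^2 / i^2) / N,
    LowGrayLevelRunEmphasis = s(function(i, l) P[i, l] / i^2) / N,
    RunEntropy = re,
    RunLengthNonUniformity = sum(lsum^2) / N,
    RunLengthNonUniformityNormalized = sum(lsum^2) / N^2,
    RunPercentage = N / np,
    RunVariance = s(function(i, l) P[i, l] / N * (l - mu_l)^2),
    ShortRunEmphasis = s(function(i, l) P[i, l] / l^2) / N,
    ShortRunHighGrayLevelEmphasis = s(function(i, l) P[i, l] * i^2 / l^2) / N,
    ShortRunLowGrayLevelEmphasis = s(function(i, l) P[i, l] / (i^2 * l^2)) / N)
}

o_glrlm_features <- function(lev, ng) {
  np <- sum(!is.na(lev))
  ds <- o_dirs()
  acc <- NULL
  for (k in seq_len(nrow(ds))) {
    f <- o_glrlm_from_matrix(o_glrlm_matrix(lev, ng, ds[k, ]), np)
    acc <- if (is.null(acc)) f else acc + f
  }
  out <- acc / nrow(ds)
  names(out) <- paste0("glrlm_", names(out))
  out
}

# -- GLSZM (flood fill) -------------------------------------------------

o_zones <- function(lev) {
  dm <- dim(lev)
  seen <- array(FALSE, dm)
  nb <- rbind(o_dirs(), -o_dirs())
  zones <- list()
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    if (seen[x, y, z] || is.na(lev[x, y, z])) next
    g <- lev[x, y, z]
    queue <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (!o_inside(q, dm)) next
        if (seen[q[1], q[2], q[3]]) next
        v <- lev[q[1], q[2], q[3]]
        if (is.na(v) || v != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(level = g, size = size)
  }
  do.call(rbind, zones)
}

o_glszm_features <- function(lev, ng) {
  np <- sum(!is.na(lev))
  zs <- o_zones(lev)
  smax <- max(zs[, "size"])
  P <- matrix(0, ng, smax)
  for (r in seq_len(nrow(zs))) P[zs[r, 1], zs[r, 2]] <- P[zs[r, 1], zs[r, 2]] + 1
  N <- sum(P)
  gsum <- rowSums(P); ssum <- colSums(P)
  mu_g <- 0; for (i in 1:ng) mu_g <- mu_g + i * gsum[i] / N
  mu_s <- 0; for (s in 1:smax) mu_s <- mu_s + s * ssum[s] / N
  acc <- function(f) { v <- 0; for (i in 1:ng) for (s in 1:smax) v <- v + f(i, s); v }
  ze <- 0
  for (i in 1:ng) for (s in 1:smax) if (P[i, s] > 0)
    ze <- ze - P[i, s] / N * log2(P[i, s] / N)
  out <- c(GrayLevelNonUniformity = sum(gsum^2) / N,
           GrayLevelNonUniformityNormalized = sum(gsum^2) / N^2,
           GrayLevelVariance = acc(function(i, s) P[i, s] / N * (i - mu_g)^2),
           HighGrayLevelZoneEmphasis = acc(function(i, s) P[i, s] * i^2) / N,
           LargeAreaEmphasis = acc(function(i, s) P[i, s] * s^2) / N,
           LargeAreaHighGrayLevelEmphasis = acc(function(i, s) P[i, s] * i^2 * s^2) / N,
           LargeAreaLowGrayLevelEmphasis = acc(function(i, s) P[i, s] * s^2 / i^2) / N,
           LowGrayLevelZoneEmphasis = acc(function(i, s) P[i, s] / i^2) / N,
           SizeZoneNonUniformity = sum(ssum^2) / N,
           SizeZoneNonUniformityNormalized = sum(ssum^2) / N^2,
           SmallAreaEmphasis = acc(function(i, s) P[i, s] / s^2) / N,
           SmallAreaHighGrayLevelEmphasis = acc(function(i, s) P[i, s] * i^2 / s^2) / N,
           SmallAreaLowGrayLevelEmphasis = acc(function(i, s) P[i, s] / (i^2 * s^2)) / N,
           ZoneEntropy = ze,
           ZonePercentage = N / np,
           ZoneVariance = acc(function(i, s) P[i, s] / N * (s - mu_s)^2))
  names(out) <- paste0("glszm_", names(out))
  out
}

# -- GLDM ---------------------------------------------------------------

o_gldm_matrix <- function(lev, ng) {
  dm <- dim(lev)
  nb <- rbind(o_dirs(), -o_dirs())
  rows <- list()
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    g <- lev[x, y, z]
    if (is.na(g)) next
    dep <- 0
    for (k in seq_len(nrow(nb))) {
      q <- c(x, y, z) + nb[k, ]
      if (!o_inside(q, dm)) next
      v <- lev[q[1], q[2], q[3]]
      if (!is.na(v) && v == g) dep <- dep + 1
    }
    rows[[length(rows) + 1]] <- c(g, dep + 1)
  }
  m <- do.call(rbind, rows)
  P <- matrix(0, ng, max(m[, 2]))
  for (r in seq_len(nrow(m))) P[m[r, 1], m[r, 2]] <- P[m[r, 1], m[r, 2]] + 1
  P
}

o_gldm_features <- function(lev, ng) {
  np <- sum(!is.na(lev))
  P <- o_gldm_matrix(lev, ng)
  nj <- ncol(P); N <- sum(P)
  gsum <- rowSums(P); jsum <- colSums(P)
  mu_g <- 0; for (i in 1:ng) mu_g <- mu_g + i * gsum[i] / N
  mu_j <- 0; for (j in 1:nj) mu_j <- mu_j + j * jsum[j] / N
  acc <- function(f) { v <- 0; for (i in 1:ng) for (j in 1:nj) v <- v + f(i, j); v }
  de <- 0
  for (i in 1:ng) for (j in 1:nj) if (P[i, j] > 0)
    de <- de - P[i, j] / N * log2(P[i, j] / N)
  out <- c(DependenceEntropy = de,
           DependenceNonUniformity = sum(jsum^2) / N,
           DependenceNonUniformityNormalized = sum(jsum^2) / N^2,
           DependenceVariance = acc(function(i, j) P[i, j] / N * (j - mu_j)^2),
           GrayLevelNonUniformity = sum(gsum^2) / N,
           GrayLevelVariance = acc(function(i, j) P[i, j] / N * (i - mu_g)^2),
           HighGrayLevelEmphasis = acc(function(i, j) P[i, j] * i^2) / N,
           LargeDependenceEmphasis = acc(function(i, j) P[i, j] * j^2) / N,
           LargeDependenceHighGrayLevelEmphasis = acc(function(i, j) P[i, j] * i^2 * j^2) / N,
           LargeDependenceLowGrayLevelEmphasis = acc(function(i, j) P[i, j] * j^2 / i^2) / N,
           LowGrayLevelEmphasis = acc(function(i, j) P[i, j] / i^2) / N,
           SmallDependenceEmphasis = acc(function(i, j) P[i, j] / j^2) / N,
           SmallDependenceHighGrayLevelEmphasis = acc(function(i, j) P[i, j] * i^2 / j^2) / N,
           SmallDependenceLowGrayLevelEmphasis = acc(function(i, j) P[i, j] / (i^2 * j^2)) / N)
  names(out) <- paste0("gldm_", names(out))
  out
}

# -- NGTDM --------------------------------------------------------------

o_ngtdm <- function(lev, ng) {
  dm <- dim(lev)
  nb <- rbind(o_dirs(), -o_dirs())
  n_i <- rep(0, ng); s_i <- rep(0, ng)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    g <- lev[x, y, z]
    if (is.na(g)) next
    vals <- c()
    for (k in seq_len(nrow(nb))) {
      q <- c(x, y, z) + nb[k, ]
      if (!o_inside(q, dm)) next
      v <- lev[q[1], q[2], q[3]]
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (!length(vals)) next
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(vals))
  }
  list(n_i = n_i, s_i = s_i, nvp = sum(n_i), p_i = n_i / sum(n_i))
}

o_ngtdm_features <- function(lev, ng) {
  st <- o_ngtdm(lev, ng)
  p <- st$p_i; s <- st$s_i; nvp <- st$nvp
  pres <- which(p > 0); ngp <- length(pres)
  ps <- 0; for (i in pres) ps <- ps + p[i] * s[i]
  coarse <- if (ps > 0) 1 / ps else 1e6
  ctr <- 0
  if (ngp > 1) {
    for (i in pres) for (j in pres) ctr <- ctr + p[i] * p[j] * (i - j)^2
    ctr <- ctr / (ngp * (ngp - 1)) * sum(s) / nvp
  }
  den <- 0; for (i in pres) for (j in pres) den <- den + abs(i * p[i] - j * p[j])
  busy <- if (den > 0) ps / den else 0
  cmplx <- 0
  for (i in pres) for (j in pres)
    cmplx <- cmplx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
  cmplx <- cmplx / nvp
  strg <- 0
  if (sum(s) > 0) {
    for (i in pres) for (j in pres) strg <- strg + (p[i] + p[j]) * (i - j)^2
    strg <- strg / sum(s)
  }
  out <- c(Busyness = busy, Coarseness = coarse, Complexity = cmplx,
           Contrast = ctr, Strength = strg)
  names(out) <- paste0("ngtdm_", names(out))
  out
}

# -- statistics oracles -------------------------------------------------

# Exact two-sided Mann-Whitney p by enumerating all C(n+m, n) group labels.
o_mw_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  dev_obs <- abs(u_obs - n * m / 2)
  combs <- utils::combn(n + m, n)
  hits <- 0
  for (c_i in seq_len(ncol(combs))) {
    xs <- pool[combs[, c_i]]
    ys <- pool[-combs[, c_i]]
    if (abs(u_of(xs, ys) - n * m / 2) >= dev_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(combs)
}

# Lin's CCC for two raters via the Pearson-accuracy decomposition
# (r times C_b), an algebraically different route from the OCCC formula.
o_lin_ccc <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  sx <- stats::sd(x) * sqrt((n - 1) / n)
  sy <- stats::sd(y) * sqrt((n - 1) / n)
  u <- (mean(x) - mean(y)) / sqrt(sx * sy)
  cb <- 2 / (sx / sy + sy / sx + u^2)
  r * cb
}

# Random masked level grid for oracle equivalence tests.
random_level_grid <- function(dm = c(4, 4, 4), ng = 4, mask_frac = 0) {
  lev <- array(sample.int(ng, prod(dm), replace = TRUE), dm)
  if (mask_frac > 0) {
    drop <- sample(length(lev), round(mask_frac * length(lev)))
    lev[drop] <- NA
  }
  if (all(is.na(lev))) lev[1] <- 1L
  ng_eff <- max(lev, na.rm = TRUE)
  # re-anchor so levels span 1..ng_eff (discretization guarantees level 1)
  lev <- lev - min(lev, na.rm = TRUE) + 1L
  list(levels = lev, n_levels = max(lev, na.rm = TRUE))
}
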