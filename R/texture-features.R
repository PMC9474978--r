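# Feature computations for the five texture-matrix families. Each exported
# function takes the discretization produced by discretize_fixed_bin_width()
# (a list with `levels`, an NA-masked integer array, and `n_levels`) and
# returns a named numeric vector with class-prefixed feature names.
#
# Degenerate regions are mapped to total, documented values rather than NaN:
# GLCM correlation and MCC of a zero-variance region are 1; information
# measures of correlation are 0 when their normalizers vanish; NGTDM
# coarseness with zero denominator is capped at 1e6 and busyness/strength
# with zero denominator are 0.

glcm_feature_names <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")

glrlm_feature_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

glszm_feature_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance")

gldm_feature_names <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

ngtdm_feature_names <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                         "Strength")

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Features of one normalized symmetric GLCM.
glcm_features_one <- function(P, ng) {
  iv <- seq_len(ng)
  I <- matrix(iv, ng, ng)
  J <- t(I)
  px <- rowSums(P)                       # = py by symmetry
  ux <- sum(iv * px)
  sigx <- sqrt(sum(px * (iv - ux)^2))
  kd <- 0:(ng - 1)
  pdiff <- vapply(kd, function(k) sum(P[abs(I - J) == k]), 0)
  ks <- 2:(2 * ng)
  psum <- vapply(ks, function(k) sum(P[I + J == k]), 0)
  da <- sum(kd * pdiff)

  hxy <- entropy2(P)
  hx <- entropy2(px)
  pp <- P > 0
  pxpy <- px[I] * px[J]
  hxy1 <- -sum(P[pp] * log2(pxpy[pp]))
  qq <- pxpy > 0
  hxy2 <- -sum(pxpy[qq] * log2(pxpy[qq]))

  corr <- if (sigx > 0) (sum(I * J * P) - ux * ux) / (sigx * sigx) else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  pos <- which(px > 0)
  mcc <- if (length(pos) < 2) 1 else {
    Pp <- P[pos, pos, drop = FALSE]
    invp <- 1 / px[pos]
    Q <- (invp * Pp) %*% (invp * Pp)   # Q[i,j] = sum_k p(i,k) p(j,k) / (px_i px_k)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }

  offd <- I != J
  c(Autocorrelation = sum(I * J * P),
    ClusterProminence = sum((I + J - 2 * ux)^4 * P),
    ClusterShade = sum((I + J - 2 * ux)^3 * P),
    ClusterTendency = sum((I + J - 2 * ux)^2 * P),
    Contrast = sum((I - J)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pdiff),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    Id = sum(P / (1 + abs(I - J))),
    Idm = sum(P / (1 + (I - J)^2)),
    Idmn = sum(P / (1 + (I - J)^2 / ng^2)),
    Idn = sum(P / (1 + abs(I - J) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[offd] / (I - J)[offd]^2),
    JointAverage = ux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * psum),
    SumEntropy = entropy2(psum),
    SumSquares = sum((I - ux)^2 * P))
}

#' Grey level co-occurrence matrix features
#'
#' Computes the 24 GLCM features at distance 1: a symmetrized, normalized
#' co-occurrence matrix is built per direction (13 unique 3D directions),
#' features are evaluated per direction and averaged. Directions that yield
#' no in-mask voxel pair are skipped; a region with no pair in any direction
#' (e.g. a single voxel) is rejected.
#'
#' @param disc discretization as returned by [discretize_fixed_bin_width()].
#' @return Named numeric vector of 24 features, prefixed `glcm_`.
#' @export
glcm_features <- function(disc) {
  lev <- disc$levels
  ng <- disc$n_levels
  dirs <- unique_directions_3d()
  acc <- NULL
  nd <- 0L
  for (k in seq_len(nrow(dirs))) {
    P <- glcm_matrix(lev, ng, dirs[k, ])
    if (is.null(P)) next
    f <- glcm_features_one(P, ng)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L)
    stop("degenerate texture region: no co-occurring voxel pairs in any direction")
  out <- acc / nd
  names(out) <- paste0("glcm_", glcm_feature_names)
  out
}

# Shared run/zone-type feature kernel: P is a counts matrix (grey level x
# size), np the number of in-mask voxels. Returns the 16 values used by both
# GLRLM (sizes = run lengths) and GLSZM (sizes = zone sizes).
size_matrix_features <- function(P, np) {
  ng <- nrow(P)
  ns <- ncol(P)
  N <- sum(P)
  iv <- seq_len(ng)
  sv <- seq_len(ns)
  pg <- rowSums(P)
  ps <- colSums(P)
  p <- P / N
  mu_g <- sum(iv * pg) / N
  mu_s <- sum(sv * ps) / N
  list(
    GrayLevelNonUniformity = sum(pg^2) / N,
    GrayLevelNonUniformityNormalized = sum(pg^2) / N^2,
    GrayLevelVariance = sum(p * (matrix(iv, ng, ns) - mu_g)^2),
    HighGrayLevel = sum(pg * iv^2) / N,
    LowGrayLevel = sum(pg / iv^2) / N,
    Large = sum(ps * sv^2) / N,
    Small = sum(ps / sv^2) / N,
    LargeHigh = sum(P * outer(iv^2, sv^2)) / N,
    LargeLow = sum(P * outer(1 / iv^2, sv^2)) / N,
    SmallHigh = sum(P * outer(iv^2, 1 / sv^2)) / N,
    SmallLow = sum(P * outer(1 / iv^2, 1 / sv^2)) / N,
    SizeNonUniformity = sum(ps^2) / N,
    SizeNonUniformityNormalized = sum(ps^2) / N^2,
    SizeVariance = sum(p * (matrix(sv, ng, ns, byrow = TRUE) - mu_s)^2),
    Entropy = entropy2(p),
    N = N)
}

#' Grey-level run-length matrix features
#'
#' Computes the 16 GLRLM features. Run-length matrices are built per
#' direction (13 unique 3D directions) with runs broken at mask boundaries;
#' features are evaluated per direction and averaged.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features, prefixed `glrlm_`.
#' @export
glrlm_features <- function(disc) {
  lev <- disc$levels
  ng <- disc$n_levels
  np <- sum(!is.na(lev))
  dirs <- unique_directions_3d()
  acc <- NULL
  for (k in seq_len(nrow(dirs))) {
    P <- glrlm_matrix(lev, ng, dirs[k, ])
    s <- size_matrix_features(P, np)
    f <- c(GrayLevelNonUniformity = s$GrayLevelNonUniformity,
           GrayLevelNonUniformityNormalized = s$GrayLevelNonUniformityNormalized,
           GrayLevelVariance = s$GrayLevelVariance,
           HighGrayLevelRunEmphasis = s$HighGrayLevel,
           LongRunEmphasis = s$Large,
           LongRunHighGrayLevelEmphasis = s$LargeHigh,
           LongRunLowGrayLevelEmphasis = s$LargeLow,
           LowGrayLevelRunEmphasis = s$LowGrayLevel,
           RunEntropy = s$Entropy,
           RunLengthNonUniformity = s$SizeNonUniformity,
           RunLengthNonUniformityNormalized = s$SizeNonUniformityNormalized,
           RunPercentage = s$N / np,
           RunVariance = s$SizeVariance,
           ShortRunEmphasis = s$Small,
           ShortRunHighGrayLevelEmphasis = s$SmallHigh,
           ShortRunLowGrayLevelEmphasis = s$SmallLow)
    acc <- if (is.null(acc)) f else acc + f
  }
  out <- acc / nrow(dirs)
  names(out) <- paste0("glrlm_", glrlm_feature_names)
  out
}

#' Grey level size zone matrix features
#'
#' Computes the 16 GLSZM features from the zones (26-connected components of
#' equal grey level within the mask). Rotation-invariant: a single matrix,
#' no direction averaging.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features, prefixed `glszm_`.
#' @export
glszm_features <- function(disc) {
  lev <- disc$levels
  ng <- disc$n_levels
  np <- sum(!is.na(lev))
  P <- glszm_matrix(lev, ng)
  s <- size_matrix_features(P, np)
  out <- c(s$GrayLevelNonUniformity, s$GrayLevelNonUniformityNormalized,
           s$GrayLevelVariance, s$HighGrayLevel, s$Large, s$LargeHigh,
           s$LargeLow, s$LowGrayLevel, s$SizeNonUniformity,
           s$SizeNonUniformityNormalized, s$Small, s$SmallHigh, s$SmallLow,
           s$Entropy, s$N / np, s$SizeVariance)
  names(out) <- paste0("glszm_", glszm_feature_names)
  out
}

#' Grey level dependence matrix features
#'
#' Computes the 14 GLDM features. The dependence of a voxel is the number of
#' its in-mask 26-neighbours with the same grey level (similarity threshold
#' 0); the matrix is indexed by (grey level, dependence + 1).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 14 features, prefixed `gldm_`.
#' @export
gldm_features <- function(disc) {
  lev <- disc$levels
  ng <- disc$n_levels
  np <- sum(!is.na(lev))
  P <- gldm_matrix(lev, ng)
  s <- size_matrix_features(P, np)
  out <- c(DependenceEntropy = s$Entropy,
           DependenceNonUniformity = s$SizeNonUniformity,
           DependenceNonUniformityNormalized = s$SizeNonUniformityNormalized,
           DependenceVariance = s$SizeVariance,
           GrayLevelNonUniformity = s$GrayLevelNonUniformity,
           GrayLevelVariance = s$GrayLevelVariance,
           HighGrayLevelEmphasis = s$HighGrayLevel,
           LargeDependenceEmphasis = s$Large,
           LargeDependenceHighGrayLevelEmphasis = s$LargeHigh,
           LargeDependenceLowGrayLevelEmphasis = s$LargeLow,
           LowGrayLevelEmphasis = s$LowGrayLevel,
           SmallDependenceEmphasis = s$Small,
           SmallDependenceHighGrayLevelEmphasis = s$SmallHigh,
           SmallDependenceLowGrayLevelEmphasis = s$SmallLow)
  names(out) <- paste0("gldm_", gldm_feature_names)
  out
}

#' Neighbouring grey tone difference matrix features
#'
#' Computes the 5 NGTDM features (busyness, coarseness, complexity,
#' contrast, strength) from per-level sums of absolute differences between
#' each voxel's level and the mean level of its in-mask 26-neighbours.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features, prefixed `ngtdm_`.
#' @export
ngtdm_features <- function(disc) {
  lev <- disc$levels
  ng <- disc$n_levels
  s <- ngtdm_summaries(lev, ng)
  p <- s$p_i
  si <- s$s_i
  nvp <- s$nvp
  iv <- seq_len(ng)
  pres <- which(p > 0)
  ngp <- length(pres)

  ps_dot <- sum(p * si)
  coarseness <- if (ps_dot > 0) 1 / ps_dot else 1e6

  contrast <- if (ngp > 1) {
    (sum(outer(p[pres], p[pres]) * outer(iv[pres], iv[pres], "-")^2) /
       (ngp * (ngp - 1))) * (sum(si) / nvp)
  } else 0

  ipi <- iv[pres] * p[pres]
  den_busy <- sum(abs(outer(ipi, ipi, "-")))
  busyness <- if (den_busy > 0) ps_dot / den_busy else 0

  pm <- outer(p[pres], p[pres], "+")
  sm <- outer(p[pres] * si[pres], p[pres] * si[pres], "+")
  dl <- abs(outer(iv[pres], iv[pres], "-"))
  complexity <- sum(dl * sm / pm) / nvp

  strength <- if (sum(si) > 0)
    sum(pm * outer(iv[pres], iv[pres], "-")^2) / sum(si) else 0

  out <- c(busyness, coarseness, complexity, contrast, strength)
  names(out) <- paste0("ngtdm_", ngtdm_feature_names)
  out
}
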