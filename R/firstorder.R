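#' Extraction settings for radiomic features
#'
#' The bin width controls fixed-bin-width grey-level discretization of HU
#' values; the voxel-array shift is added to intensities before energy-type
#' computations so that squared sums are taken over non-negative values on
#' the CT scale (air at -1000 HU maps to 0).
#'
#' @param bin_width discretization bin width in HU (> 0); default 25.
#' @param voxel_array_shift shift `c` added to intensities for energy, total
#'   energy and root-mean-squared; default 1000.
#' @return An object of class `extraction_settings`.
#' @export
extraction_settings <- function(bin_width = 25, voxel_array_shift = 1000) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive value (HU)")
  if (!is.numeric(voxel_array_shift) || length(voxel_array_shift) != 1L ||
      !is.finite(voxel_array_shift))
    stop("`voxel_array_shift` must be a single finite value (HU)")
  structure(list(bin_width = bin_width, voxel_array_shift = voxel_array_shift),
            class = "extraction_settings")
}

fo_names <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
              "90Percentile", "Maximum", "Mean", "Median",
              "InterquartileRange", "Range", "MeanAbsoluteDeviation",
              "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
              "Kurtosis", "Variance", "Uniformity")

# x: in-mask intensities; lev: matching in-mask grey levels; vox_vol: mm^3.
# Entropy and uniformity are functionals of the discretized histogram;
# kurtosis is reported uncentred (a normal sample tends to 3, not 0);
# skewness/kurtosis of a constant sample are defined as 0.
first_order_values <- function(x, lev, vox_vol, settings) {
  n <- length(x)
  shift <- settings$voxel_array_shift
  p <- tabulate(lev) / n
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  sel <- x[x >= q[1] & x <= q[4]]
  energy <- sum((x + shift)^2)
  c(Energy = energy,
    TotalEnergy = vox_vol * energy,
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = mu,
    Median = stats::median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(sel - mean(sel))),
    RootMeanSquared = sqrt(energy / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}
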