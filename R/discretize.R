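#' Fixed-bin-width grey-level discretization
#'
#' Maps in-mask intensities to integer grey levels with bins of constant
#' width anchored at the in-mask minimum:
#' `level(x) = floor((x - min) / w) + 1`. The in-mask minimum maps to level 1
#' and the in-mask maximum to the highest level `Ng`. Positions outside the
#' mask (encoded as `NA` in `values`) stay `NA`.
#'
#' @param values numeric array (or vector) of intensities; `NA` marks
#'   out-of-mask positions.
#' @param bin_width bin width `w` in intensity units (> 0).
#' @return A list with `levels` (integer, same shape as `values`),
#'   `n_levels` (`Ng`), and `min_value` (the bin anchor).
#' @export
#' @examples
#' discretize_fixed_bin_width(c(0, 24.9), 25)$levels  # both level 1
#' discretize_fixed_bin_width(c(0, 25), 25)$levels    # levels 1 and 2
discretize_fixed_bin_width <- function(values, bin_width) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive value")
  inside <- !is.na(values)
  if (!any(inside)) stop("empty VOI: no in-mask voxels to discretize")
  mn <- min(values[inside])
  lev <- values
  lev[inside] <- floor((values[inside] - mn) / bin_width) + 1
  storage.mode(lev) <- "integer"
  list(levels = lev, n_levels = max(lev[inside]), min_value = mn)
}
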