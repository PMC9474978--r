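#' 3D image volume with spatial metadata
#'
#' Lightweight container for a 3D scalar grid (Hounsfield units for CT data)
#' together with its voxel spacing and origin in millimetres. The origin is
#' the world-space position of the centre of voxel `[1, 1, 1]`; the centre of
#' voxel `i` along an axis sits at `origin + (i - 1) * spacing`.
#'
#' @param data numeric 3D array of voxel values.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm position of the first voxel centre.
#'
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `spacing` and `origin`.
#' @export
#' @examples
#' vol <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(vol)
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' World coordinates of voxel centres, per axis
#'
#' @param vol an [image_volume].
#' @return A list of three numeric vectors: the centre coordinate (mm) of
#'   every voxel along each axis.
#' @export
axis_centres <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  lapply(1:3, function(a)
    vol$origin[a] + (seq_len(dim(vol$data)[a]) - 1) * vol$spacing[a])
}

#' Physical volume of one voxel in mm^3
#'
#' @param vol an [image_volume].
#' @return Scalar, mm^3.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
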