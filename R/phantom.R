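#' Geometry of the simulated saline-cup phantom
#'
#' Describes a homogeneous cylindrical body (the saline-filled cup) embedded
#' in air, on a regular CT-like voxel grid. The default grid is a desk-scale
#' 96 x 96 x 96 volume at 1 mm isotropic spacing; clinical-resolution grids
#' (e.g. 512 x 512 at 0.43 x 0.43 x 0.5 mm) are selectable through the same
#' arguments. The cylinder axis runs along the third (z) axis and the body is
#' centred in the volume.
#'
#' @param vol_dim integer length-3, voxel counts per axis.
#' @param spacing numeric length-3, mm per voxel; all > 0.
#' @param origin numeric length-3, mm position of the first voxel centre.
#' @param body_radius cylinder radius in mm.
#' @param body_height cylinder height in mm.
#' @param body_value mean HU of the homogeneous body (saline is close to
#'   water, slightly positive).
#' @param background_value HU of the surrounding air.
#' @param margin_mm minimum clearance (mm) required between the body surface
#'   and every face of the volume, so that the largest VOI plus a ring of map
#'   blocks never touches the boundary.
#'
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(vol_dim = c(96, 96, 96),
                             spacing = c(1, 1, 1),
                             origin = c(0, 0, 0),
                             body_radius = 28,
                             body_height = 56,
                             body_value = 5,
                             background_value = -1000,
                             margin_mm = 10) {
  vol_dim <- as.integer(vol_dim)
  spacing <- as.numeric(spacing)
  if (length(vol_dim) != 3L || any(vol_dim < 1L))
    stop("`vol_dim` must be three positive voxel counts")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  if (body_radius <= 0 || body_height <= 0)
    stop("body radius and height must be positive (mm)")
  geom <- structure(list(vol_dim = vol_dim, spacing = spacing,
                         origin = as.numeric(origin),
                         body_radius = body_radius, body_height = body_height,
                         body_value = body_value,
                         background_value = background_value,
                         margin_mm = margin_mm),
                    class = "phantom_geometry")
  half <- vol_dim * spacing / 2
  if (body_radius + margin_mm > half[1] || body_radius + margin_mm > half[2] ||
      body_height / 2 + margin_mm > half[3])
    stop("phantom body does not fit inside the volume with a ",
         margin_mm, " mm margin")
  geom
}

#' World-space centre of the phantom body
#'
#' The body centre is fixed in world coordinates: repositioning between scans
#' is modelled by shifting the scan grid (the volume origin), not the body.
#' VOIs track this point.
#'
#' @param geometry a [phantom_geometry].
#' @return numeric length-3, mm.
#' @export
body_centre <- function(geometry) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  geometry$origin + (geometry$vol_dim - 1) * geometry$spacing / 2
}

#' Additive Gaussian noise model
#'
#' White Gaussian noise added to every voxel, a simple stand-in for CT image
#' noise. `sigma = 0` yields a deterministic volume.
#'
#' @param sigma noise standard deviation in HU (>= 0).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 10, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative value (HU)")
  structure(list(kind = "additive-gaussian", sigma = sigma, seed = seed),
            class = "noise_model")
}

#' Simulate a single phantom scan
#'
#' Rasterizes the cylindrical body on the scan grid and adds voxel-wise
#' Gaussian noise. Repositioning is expressed through `offset`: the scan
#' grid's origin is shifted by `offset` while the body stays at its fixed
#' world position, so the body appears displaced relative to the grid --
#' exactly what happens when a phantom is moved inside a fixed scanner.
#'
#' A voxel takes the body value iff its centre lies inside the cylinder;
#' all other voxels take the background value.
#'
#' @param geometry a [phantom_geometry].
#' @param noise a [noise_model]; its `seed` (if non-`NULL`) makes the scan
#'   reproducible.
#' @param offset numeric length-3, mm shift of the scan grid (repositioning).
#' @return An [image_volume] in HU.
#' @export
#' @examples
#' g <- phantom_geometry(vol_dim = c(48, 48, 48), body_radius = 12,
#'                       body_height = 24)
#' scan <- generate_phantom_scan(g, noise_model(sigma = 0))
#' range(scan$data)
generate_phantom_scan <- function(geometry, noise = noise_model(),
                                  offset = c(0, 0, 0)) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(noise, "noise_model"))
  offset <- as.numeric(offset)
  if (length(offset) != 3L || any(!is.finite(offset)))
    stop("`offset` must be three finite values (mm)")

  org <- geometry$origin + offset
  ctr <- body_centre(geometry)
  dm <- geometry$vol_dim
  sp <- geometry$spacing

  # body must stay fully inside the (shifted) volume
  lo <- org - sp / 2
  hi <- org + (dm - 0.5) * sp
  if (ctr[1] - geometry$body_radius < lo[1] || ctr[1] + geometry$body_radius > hi[1] ||
      ctr[2] - geometry$body_radius < lo[2] || ctr[2] + geometry$body_radius > hi[2] ||
      ctr[3] - geometry$body_height / 2 < lo[3] || ctr[3] + geometry$body_height / 2 > hi[3])
    stop("offset moves the phantom body partially outside the scan volume")

  cx <- org[1] + (seq_len(dm[1]) - 1) * sp[1]
  cy <- org[2] + (seq_len(dm[2]) - 1) * sp[2]
  cz <- org[3] + (seq_len(dm[3]) - 1) * sp[3]
  in_xy <- outer((cx - ctr[1])^2, (cy - ctr[2])^2, "+") <= geometry$body_radius^2
  in_z <- abs(cz - ctr[3]) <= geometry$body_height / 2
  in_body <- outer(in_xy, in_z, "&")

  vox <- array(geometry$background_value, dm)
  vox[in_body] <- geometry$body_value
  if (noise$sigma > 0) {
    vox <- vox + with_seed(noise$seed,
                           array(stats::rnorm(prod(dm), 0, noise$sigma), dm))
  }
  image_volume(vox, spacing = sp, origin = org)
}

#' Simulate a repositioned scan series
#'
#' Generates `n` scans of the same phantom, each with its own derived seed
#' (`base_seed + scan index`) and an independent uniform repositioning offset
#' in `[-jitter_mm, +jitter_mm]` per axis. All scans share shape and spacing;
#' only the origins differ, by the applied jitter.
#'
#' @param geometry a [phantom_geometry].
#' @param noise a [noise_model]; its own `seed` field is ignored in favour of
#'   the per-scan derived seeds.
#' @param n number of scans (>= 2; stability statistics need repeats).
#' @param jitter_mm maximum absolute repositioning offset per axis, mm.
#' @param base_seed integer master seed.
#' @return An object of class `scan_series`: list with `scans` (list of
#'   [image_volume]), `offsets` (n x 3 matrix, mm), `seeds`, `jitter_mm`,
#'   `geometry` and `noise`.
#' @export
generate_scan_series <- function(geometry, noise = noise_model(), n = 10,
                                 jitter_mm = 2, base_seed = 1) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(noise, "noise_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("`n` must be >= 2: stability statistics are undefined for a single scan")
  n <- as.integer(n)
  if (jitter_mm < 0) stop("`jitter_mm` must be non-negative")

  seeds <- as.integer(base_seed + seq_len(n))
  offsets <- matrix(0, n, 3)
  scans <- vector("list", n)
  for (s in seq_len(n)) {
    scans[[s]] <- with_seed(seeds[s], {
      off <- stats::runif(3, -jitter_mm, jitter_mm)
      offsets[s, ] <- off
      generate_phantom_scan(geometry,
                            noise_model(sigma = noise$sigma, seed = NULL),
                            offset = off)
    })
  }
  structure(list(scans = scans, offsets = offsets, seeds = seeds,
                 jitter_mm = jitter_mm, geometry = geometry, noise = noise),
            class = "scan_series")
}

#' @export
print.scan_series <- function(x, ...) {
  cat("<scan_series> ", length(x$scans), " scans of ",
      paste(x$geometry$vol_dim, collapse = " x "), " voxels, sigma = ",
      x$noise$sigma, " HU, jitter = ", x$jitter_mm, " mm\n", sep = "")
  invisible(x)
}
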