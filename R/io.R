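# NIfTI-1 I/O for image volumes and feature map sets. Spacing and origin are
# carried in the sform (and pixdim); values are stored as float64 so that
# save/load round trips are bit-exact.

#' Write an image volume as NIfTI-1
#'
#' @param vol an [image_volume].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  dm <- dim(vol$data)
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, dm, 1L, 1L, 1L, 1L),
    pixdim = c(-1, vol$spacing, 0, 0, 0, 0),
    srow_x = c(vol$spacing[1], 0, 0, vol$origin[1]),
    srow_y = c(0, vol$spacing[2], 0, vol$origin[2]),
    srow_z = c(0, 0, vol$spacing[3], vol$origin[3]),
    sform_code = 2L, qform_code = 0L, datatype = 64L))
  img <- RNifti::asNifti(vol$data, reference = hdr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as an image_volume
#'
#' Spacing and origin are taken from the stored transform; only axis-aligned
#' volumes (diagonal rotation part) are accepted.
#'
#' @param path NIfTI file path.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (any(abs(rot[row(rot) != col(rot)]) > 1e-6))
    stop("only axis-aligned volumes are supported")
  sp <- diag(rot)
  if (any(sp <= 0)) stop("unsupported axis orientation in ", path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  image_volume(arr, spacing = sp, origin = xf[1:3, 4])
}

#' Save a scan series to a directory
#'
#' One NIfTI file per scan (`scan_001.nii.gz`, ...) plus a JSON manifest
#' with seeds, offsets and the phantom geometry.
#'
#' @param series a `scan_series` from [generate_scan_series()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_scan_series <- function(series, dir) {
  stopifnot(inherits(series, "scan_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("scan_%03d.nii.gz", seq_along(series$scans))
  for (s in seq_along(series$scans))
    write_volume(series$scans[[s]], file.path(dir, files[s]))
  g <- series$geometry
  manifest <- list(
    n_scans = length(series$scans), files = files,
    seeds = series$seeds, offsets_mm = series$offsets,
    jitter_mm = series$jitter_mm, noise_sigma = series$noise$sigma,
    geometry = list(vol_dim = g$vol_dim, spacing = g$spacing,
                    origin = g$origin, body_radius = g$body_radius,
                    body_height = g$body_height, body_value = g$body_value,
                    background_value = g$background_value))
  jsonlite::write_json(manifest, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Save a feature map set to a directory
#'
#' One NIfTI file per feature map plus a `maps.json` manifest recording the
#' feature list, block edge, extraction settings and source geometry. The
#' round trip through [load_maps()] is bit-exact.
#'
#' @param maps a `feature_map_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "feature_map_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(names(maps$maps), ".nii.gz")
  for (f in seq_along(maps$maps))
    write_volume(maps$maps[[f]], file.path(dir, files[f]))
  manifest <- list(features = names(maps$maps), files = files,
                   block_mm = maps$block_mm,
                   settings = list(bin_width = maps$settings$bin_width,
                                   voxel_array_shift = maps$settings$voxel_array_shift),
                   source = maps$source,
                   map_dim = dim(maps$maps[[1]]$data),
                   map_origin = maps$maps[[1]]$origin)
  jsonlite::write_json(manifest, file.path(dir, "maps.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a feature map set saved by save_maps
#'
#' @param dir directory containing `maps.json` and the per-feature NIfTI
#'   files.
#' @return A `feature_map_set`.
#' @export
load_maps <- function(dir) {
  mpath <- file.path(dir, "maps.json")
  if (!file.exists(mpath)) stop("no maps.json manifest in ", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  missing <- !file.exists(file.path(dir, man$files))
  if (any(missing))
    stop("manifest lists missing map file(s): ",
         paste(man$files[missing], collapse = ", "))
  maps <- lapply(file.path(dir, man$files), read_volume)
  names(maps) <- man$features
  ref <- maps[[1]]
  if (!identical(dim(ref$data), as.integer(man$map_dim)) ||
      any(abs(ref$origin - man$map_origin) > 1e-6) ||
      any(abs(ref$spacing - man$block_mm) > 1e-6))
    stop("map files do not match the manifest's spatial metadata")
  for (m in maps)
    if (!identical(dim(m$data), dim(ref$data)))
      stop("map files disagree in shape")
  structure(list(maps = maps, block_mm = man$block_mm, grid = NULL,
                 settings = extraction_settings(man$settings$bin_width,
                                                man$settings$voxel_array_shift),
                 source = man$source),
            class = "feature_map_set")
}
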