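#' Plan a fixed-size block grid over a volume
#'
#' Tiles the volume with disjoint cubic blocks of edge `block_mm`, starting
#' at the volume origin plus an optional alignment shift. Only whole blocks
#' inside the volume are kept; partial boundary blocks are dropped. The
#' block edge must be an integer multiple of the voxel spacing on every axis
#' (see [resample_for_blocks()] when it is not).
#'
#' @param volume an [image_volume].
#' @param block_mm block edge length in mm (default 4).
#' @param alignment_mm numeric length-3 shift of the grid start relative to
#'   the volume origin; must be a whole number of voxels per axis.
#' @return An object of class `block_grid`.
#' @export
#' @examples
#' vol <- image_volume(array(0, c(96, 96, 96)))
#' g <- plan_block_grid(vol, 4)
#' g$n_blocks   # 24 24 24
plan_block_grid <- function(volume, block_mm = 4, alignment_mm = c(0, 0, 0)) {
  stopifnot(inherits(volume, "image_volume"))
  sp <- volume$spacing
  dm <- dim(volume$data)
  if (block_mm < max(sp))
    stop("block edge (", block_mm, " mm) is smaller than one source voxel")
  vpb <- block_mm / sp
  if (any(abs(vpb - round(vpb)) > 1e-8))
    stop("block edge must be an integer multiple of the voxel spacing on ",
         "every axis; resample the volume first (see resample_for_blocks)")
  vpb <- as.integer(round(vpb))
  av <- alignment_mm / sp
  if (any(abs(av - round(av)) > 1e-8))
    stop("`alignment_mm` must be a whole number of voxels per axis")
  av <- as.integer(round(av))
  if (any(av < 0) || any(av >= dm))
    stop("`alignment_mm` places the grid start outside the volume")
  n_blocks <- (dm - av) %/% vpb
  if (any(n_blocks < 1L))
    stop("volume too small to hold a single whole block")
  start <- av + 1L
  structure(list(block_mm = block_mm, vpb = vpb, start = start,
                 n_blocks = n_blocks, spacing = sp, origin = volume$origin,
                 vol_dim = dm,
                 map_origin = volume$origin + (start - 1 + (vpb - 1) / 2) * sp),
            class = "block_grid")
}

#' @export
print.block_grid <- function(x, ...) {
  cat("<block_grid> ", paste(x$n_blocks, collapse = " x "), " blocks of ",
      x$block_mm, " mm (", paste(x$vpb, collapse = " x "),
      " voxels each)\n", sep = "")
  invisible(x)
}

# World-space centres of block k (per axis) for a grid.
block_centres <- function(grid) {
  lapply(1:3, function(a)
    grid$map_origin[a] + (seq_len(grid$n_blocks[a]) - 1) * grid$block_mm)
}

#' Resample a volume to a spacing that divides the block edge
#'
#' Nearest-neighbour resampling onto an isotropic grid of spacing
#' `block_mm / k` (the largest such spacing not exceeding the finest source
#' spacing), so that block tiling is exact. Only needed when the source
#' spacing does not divide the block edge.
#'
#' @param volume an [image_volume].
#' @param block_mm intended block edge, mm.
#' @return An [image_volume] with the new spacing; the extent is trimmed to
#'   the source extent.
#' @export
resample_for_blocks <- function(volume, block_mm = 4) {
  stopifnot(inherits(volume, "image_volume"))
  k <- ceiling(block_mm / min(volume$spacing))
  new_sp <- rep(block_mm / k, 3)
  dm <- dim(volume$data)
  new_dm <- floor(dm * volume$spacing / new_sp)
  ctr <- lapply(1:3, function(a)
    volume$origin[a] + (seq_len(new_dm[a]) - 1) * new_sp[a])
  idx <- lapply(1:3, function(a)
    pmin(dm[a], pmax(1L, as.integer(round((ctr[[a]] - volume$origin[a]) /
                                            volume$spacing[a])) + 1L)))
  image_volume(volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               spacing = new_sp, origin = volume$origin)
}

#' Compute parametric feature maps on a block grid
#'
#' For every block of the grid, the requested features are computed with the
#' block's voxels as their own mask (per-block min-anchored discretization,
#' identical semantics to per-VOI extraction), and the value is stored at
#' the block's position in a per-feature map volume. Map voxels sit at block
#' centres with spacing equal to the block edge, so maps carry the same
#' spatial reference as the source image.
#'
#' @param volume the source [image_volume] the grid was planned on.
#' @param grid a [block_grid] from [plan_block_grid()].
#' @param settings an [extraction_settings].
#' @param features character vector of feature names (default: all 93).
#' @return An object of class `feature_map_set`: list with `maps` (named
#'   list of [image_volume], one per feature), `block_mm`, `grid`,
#'   `settings` and `source` metadata.
#' @export
compute_feature_maps <- function(volume, grid,
                                 settings = extraction_settings(),
                                 features = feature_names()) {
  stopifnot(inherits(volume, "image_volume"), inherits(grid, "block_grid"))
  if (!identical(dim(volume$data), grid$vol_dim) ||
      any(abs(volume$spacing - grid$spacing) > 1e-9) ||
      any(abs(volume$origin - grid$origin) > 1e-9))
    stop("`grid` was not planned on this volume")
  classes <- classes_for_features(features)   # rejects unknown names
  nb <- grid$n_blocks
  vpb <- grid$vpb
  vox_vol <- voxel_volume(volume)
  vals <- matrix(NA_real_, prod(nb), length(features),
                 dimnames = list(NULL, features))
  bi <- 0L
  for (k in seq_len(nb[3])) {
    zr <- grid$start[3] + (k - 1L) * vpb[3] + seq_len(vpb[3]) - 1L
    for (j in seq_len(nb[2])) {
      yr <- grid$start[2] + (j - 1L) * vpb[2] + seq_len(vpb[2]) - 1L
      for (i in seq_len(nb[1])) {
        xr <- grid$start[1] + (i - 1L) * vpb[1] + seq_len(vpb[1]) - 1L
        block <- volume$data[xr, yr, zr, drop = FALSE]
        fv <- extract_features_core(block, vox_vol, settings, classes)
        # linear index in (i fastest) order matches array filling below
        vals[i + (j - 1L) * nb[1] + (k - 1L) * nb[1] * nb[2], ] <-
          fv[features]
        bi <- bi + 1L
      }
    }
  }
  maps <- lapply(seq_along(features), function(f)
    image_volume(array(vals[, f], nb), spacing = rep(grid$block_mm, 3),
                 origin = grid$map_origin))
  names(maps) <- features
  structure(list(maps = maps, block_mm = grid$block_mm, grid = grid,
                 settings = settings,
                 source = list(dim = dim(volume$data),
                               spacing = volume$spacing,
                               origin = volume$origin)),
            class = "feature_map_set")
}

#' @export
print.feature_map_set <- function(x, ...) {
  cat("<feature_map_set> ", length(x$maps), " maps of ",
      paste(dim(x$maps[[1]]$data), collapse = " x "), " blocks (",
      x$block_mm, " mm edge)\n", sep = "")
  invisible(x)
}

#' Crop a volume to whole blocks around a point
#'
#' Returns the sub-volume consisting of all whole blocks (edge `block_mm`,
#' grid aligned to the volume origin) whose centres lie within
#' `half_width_mm` of `centre_mm` on every axis. Cropping at block
#' boundaries keeps the block grid of the crop identical to the
#' corresponding part of the full-volume grid.
#'
#' @param volume an [image_volume].
#' @param centre_mm numeric length-3, mm.
#' @param half_width_mm scalar half-width of the region, mm.
#' @param block_mm block edge, mm.
#' @return An [image_volume].
#' @export
crop_volume_blocks <- function(volume, centre_mm, half_width_mm,
                               block_mm = 4) {
  grid <- plan_block_grid(volume, block_mm)
  ctr <- block_centres(grid)
  sel <- lapply(1:3, function(a)
    which(abs(ctr[[a]] - centre_mm[a]) <= half_width_mm + 1e-9))
  if (any(vapply(sel, length, 1L) == 0L))
    stop("no block centres within the requested region")
  vr <- lapply(1:3, function(a) {
    ks <- range(sel[[a]])
    (grid$start[a] + (ks[1] - 1L) * grid$vpb[a]):
      (grid$start[a] + ks[2] * grid$vpb[a] - 1L)
  })
  image_volume(volume$data[vr[[1]], vr[[2]], vr[[3]], drop = FALSE],
               spacing = volume$spacing,
               origin = volume$origin + (vapply(vr, `[`, 1L, 1) - 1) *
                 volume$spacing)
}
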