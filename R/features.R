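feature_classes <- c("firstorder", "glcm", "gldm", "glrlm", "glszm", "ngtdm")

#' The 93-feature inventory
#'
#' Names of all features computed by [extract_features()]: 18 first-order,
#' 24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM and 5 NGTDM, each prefixed by its
#' class. Shape features are deliberately absent: their dependence on VOI
#' size is trivial.
#'
#' @param classes character vector of class prefixes to include; default all
#'   six.
#' @return Character vector of feature names.
#' @export
#' @examples
#' length(feature_names())          # 93
#' feature_names("ngtdm")
feature_names <- function(classes = feature_classes) {
  classes <- match.arg(classes, feature_classes, several.ok = TRUE)
  unlist(lapply(classes, function(cl) {
    nm <- switch(cl,
                 firstorder = fo_names,
                 glcm = glcm_feature_names,
                 gldm = gldm_feature_names,
                 glrlm = glrlm_feature_names,
                 glszm = glszm_feature_names,
                 ngtdm = ngtdm_feature_names)
    paste0(cl, "_", nm)
  }), use.names = FALSE)
}

# Classes needed to produce a set of feature names.
classes_for_features <- function(features) {
  cl <- unique(sub("_.*$", "", features))
  unknown <- setdiff(features, feature_names())
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  feature_classes[feature_classes %in% cl]
}

# Core extractor on an NA-masked numeric array (already cropped to the mask
# bounding box). `classes` restricts computation to the listed families.
extract_features_core <- function(varr, vox_vol, settings,
                                  classes = feature_classes) {
  inside <- !is.na(varr)
  if (!any(inside)) stop("empty VOI: mask contains no voxels")
  disc <- discretize_fixed_bin_width(varr, settings$bin_width)
  out <- numeric(0)
  for (cl in classes) {
    f <- tryCatch(switch(cl,
                         firstorder = first_order_values(varr[inside],
                                                         disc$levels[inside],
                                                         vox_vol, settings),
                         glcm = glcm_features(disc),
                         gldm = gldm_features(disc),
                         glrlm = glrlm_features(disc),
                         glszm = glszm_features(disc),
                         ngtdm = ngtdm_features(disc)),
                  error = function(e)
                    stop(cl, " feature computation failed: ",
                         conditionMessage(e), call. = FALSE))
    if (cl == "firstorder") names(f) <- paste0("firstorder_", names(f))
    out <- c(out, f)
  }
  out
}

#' Extract radiomic features from a masked volume
#'
#' Computes the full 93-feature inventory (or a class subset) over the
#' voxels selected by `mask`. Intensities are discretized per VOI with a
#' fixed bin width anchored at the in-mask minimum; energy-type features use
#' intensities shifted by the voxel-array shift.
#'
#' @param volume an [image_volume] (or bare 3D array, assumed 1 mm
#'   isotropic).
#' @param mask logical 3D array of the same shape; `TRUE` marks VOI voxels.
#' @param settings an [extraction_settings].
#' @param classes feature classes to compute (default: all six).
#' @return Named numeric vector; with all classes, exactly 93 values.
#' @export
#' @examples
#' vol <- image_volume(array(rnorm(8^3, 0, 10), c(8, 8, 8)))
#' mask <- array(TRUE, c(8, 8, 8))
#' length(extract_features(vol, mask))
extract_features <- function(volume, mask, settings = extraction_settings(),
                             classes = feature_classes) {
  if (!inherits(volume, "image_volume"))
    volume <- image_volume(volume)
  stopifnot(inherits(settings, "extraction_settings"))
  if (!is.array(mask) || !identical(dim(mask), dim(volume$data)))
    stop("`mask` must be an array with the same shape as the volume")
  mask <- as.logical(mask) & !is.na(mask)
  dim(mask) <- dim(volume$data)
  if (!any(mask)) stop("empty VOI: mask contains no voxels")
  classes <- match.arg(classes, feature_classes, several.ok = TRUE)

  # crop to the mask bounding box; NA marks out-of-mask voxels
  rng <- lapply(1:3, function(a) range(which(apply(mask, a, any))))
  varr <- volume$data[rng[[1]][1]:rng[[1]][2],
                      rng[[2]][1]:rng[[2]][2],
                      rng[[3]][1]:rng[[3]][2], drop = FALSE]
  msk <- mask[rng[[1]][1]:rng[[1]][2],
              rng[[2]][1]:rng[[2]][2],
              rng[[3]][1]:rng[[3]][2], drop = FALSE]
  varr[!msk] <- NA_real_
  extract_features_core(varr, voxel_volume(volume), settings, classes)
}
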