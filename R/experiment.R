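#' Configuration of the VOI-stability experiment
#'
#' Bundles every knob of the end-to-end study: phantom geometry and noise,
#' number of scans and repositioning jitter, VOI diameters, block edge of
#' the parametric maps, extraction settings, and the statistical thresholds
#' (alpha for the Bonferroni-adjusted Mann-Whitney tests, OCCC cutoff for
#' excellent agreement).
#'
#' @param geometry a [phantom_geometry].
#' @param noise a [noise_model].
#' @param n_scans number of repeated scans (default 10).
#' @param jitter_mm repositioning jitter per axis, mm (default 2).
#' @param voi_diameters VOI diameters in mm, smallest to largest (default
#'   4, 8, 16).
#' @param block_mm parametric-map block edge, mm (default 4).
#' @param settings an [extraction_settings].
#' @param alpha significance level (default 0.05).
#' @param occc_cutoff excellent-agreement OCCC threshold (default 0.85).
#' @param map_roi_half_width half-width (mm) of the block-aligned region
#'   around the phantom centre over which maps are computed; the default
#'   covers the largest VOI plus jitter plus one half-block, the minimum
#'   that guarantees every in-sphere map voxel exists. `Inf` computes maps
#'   over the whole volume.
#' @param master_seed integer seed driving all randomness.
#' @param features feature names to analyse (default: all 93).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(geometry = phantom_geometry(),
                              noise = noise_model(sigma = 10),
                              n_scans = 10,
                              jitter_mm = 2,
                              voi_diameters = c(4, 8, 16),
                              block_mm = 4,
                              settings = extraction_settings(),
                              alpha = 0.05,
                              occc_cutoff = 0.85,
                              map_roi_half_width = NULL,
                              master_seed = 1,
                              features = feature_names()) {
  if (length(voi_diameters) != 3L || is.unsorted(voi_diameters, strictly = TRUE))
    stop("`voi_diameters` must be three increasing diameters (mm)")
  if (is.null(map_roi_half_width))
    map_roi_half_width <- max(voi_diameters) / 2 + jitter_mm + block_mm / 2
  structure(list(geometry = geometry, noise = noise, n_scans = n_scans,
                 jitter_mm = jitter_mm, voi_diameters = voi_diameters,
                 block_mm = block_mm, settings = settings, alpha = alpha,
                 occc_cutoff = occc_cutoff,
                 map_roi_half_width = map_roi_half_width,
                 master_seed = master_seed, features = features),
            class = "experiment_config")
}

#' Run the full VOI-stability experiment
#'
#' Simulates the repositioned scan series, extracts all features per VOI
#' size both conventionally (VOI rasterized on the source grid) and from
#' parametric maps (VOI mean over block-grid map voxels), then runs the
#' pairwise Mann-Whitney tests and OCCC agreement analysis for both modes.
#' Deterministic given `config$master_seed`.
#'
#' @param config an [experiment_config].
#' @param out_dir optional directory: when given, per-feature tables, the
#'   summary JSON and the measurement tables are written via
#'   [write_report()].
#' @param verbose print per-stage progress.
#' @return An object of class `stability_report`: list with `records`
#'   (per-feature, per-mode statistics), `counts` (headline counts),
#'   `tables` (n x J x feature measurement arrays per mode), `config` and
#'   `provenance`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  feats <- config$features
  dias <- config$voi_diameters
  n <- config$n_scans
  dnames <- paste0("d", dias)

  say <- function(...) if (verbose) message(...)
  say("simulating ", n, " phantom scans")
  series <- generate_scan_series(config$geometry, config$noise, n = n,
                                 jitter_mm = config$jitter_mm,
                                 base_seed = config$master_seed)
  ctr <- body_centre(config$geometry)

  tabs <- list(
    conventional = array(NA_real_, c(n, length(dias), length(feats)),
                         dimnames = list(NULL, dnames, feats)),
    map = array(NA_real_, c(n, length(dias), length(feats)),
                dimnames = list(NULL, dnames, feats)))
  fallback <- matrix(FALSE, n, length(dias), dimnames = list(NULL, dnames))

  for (s in seq_len(n)) {
    vol <- series$scans[[s]]
    say("scan ", s, ": conventional extraction")
    for (j in seq_along(dias)) {
      fv <- conventional_extract(vol, spherical_voi(ctr, dias[j]),
                                 config$settings)
      tabs$conventional[s, j, ] <- fv[feats]
    }
    say("scan ", s, ": parametric maps")
    mvol <- if (is.finite(config$map_roi_half_width))
      crop_volume_blocks(vol, ctr, config$map_roi_half_width,
                         config$block_mm)
    else vol
    grid <- plan_block_grid(mvol, config$block_mm)
    maps <- compute_feature_maps(mvol, grid, config$settings, feats)
    for (j in seq_along(dias)) {
      rv <- map_readout(maps, spherical_voi(ctr, dias[j]))
      fallback[s, j] <- isTRUE(attr(rv, "fallback_nearest"))
      tabs$map[s, j, ] <- rv[feats]
    }
  }

  say("stability statistics")
  records <- do.call(rbind, lapply(c("conventional", "map"), function(mode) {
    do.call(rbind, lapply(feats, function(f) {
      tb <- tabs[[mode]][, , f]
      tests <- pairwise_voi_tests(tb, alpha = config$alpha)
      o3 <- as.numeric(occc(tb))
      o2 <- as.numeric(occc(tb[, 2:3]))
      data.frame(feature = f, class = sub("_.*$", "", f), mode = mode,
                 p_adj_1_2 = tests$p_adj[1], p_adj_1_3 = tests$p_adj[2],
                 p_adj_2_3 = tests$p_adj[3],
                 sig_1_2 = tests$significant[1],
                 sig_1_3 = tests$significant[2],
                 sig_2_3 = tests$significant[3],
                 sig_any = any(tests$significant),
                 occc_all = o3, occc_upper = o2,
                 stable_all = classify_stability(o3, config$occc_cutoff),
                 stable_upper = classify_stability(o2, config$occc_cutoff))
    }))
  }))
  rownames(records) <- NULL

  counts <- summarize_counts(records)
  report <- structure(
    list(records = records, counts = counts, tables = tabs,
         map_fallback = fallback, config = config,
         provenance = list(master_seed = config$master_seed,
                           scan_seeds = series$seeds,
                           offsets_mm = series$offsets,
                           package_version =
                             as.character(utils::packageVersion("radiomaps")))),
    class = "stability_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Headline counts from per-feature stability records
#'
#' Tallies, for each extraction mode, how many features are significantly
#' different between VOI sizes (any pair and per pair), how many features'
#' OCCC increases in map mode relative to conventional mode, and how many
#' map-mode features reach the excellent-agreement cutoff.
#'
#' @param records the `records` data.frame of a `stability_report`, holding
#'   both modes for the same feature set.
#' @return Named list of counts.
#' @export
summarize_counts <- function(records) {
  need <- c("feature", "mode", "sig_1_2", "sig_1_3", "sig_2_3", "sig_any",
            "occc_all", "occc_upper", "stable_all", "stable_upper")
  if (!all(need %in% names(records))) stop("malformed records table")
  conv <- records[records$mode == "conventional", ]
  mp <- records[records$mode == "map", ]
  if (nrow(conv) != nrow(mp) || !setequal(conv$feature, mp$feature))
    stop("records must hold the same features for both modes")
  mp <- mp[match(conv$feature, mp$feature), ]
  counts <- list(
    n_features = nrow(conv),
    sig_any_conventional = sum(conv$sig_any),
    sig_any_map = sum(mp$sig_any),
    sig_map_pair_1_2 = sum(mp$sig_1_2),
    sig_map_pair_1_3 = sum(mp$sig_1_3),
    sig_map_pair_2_3 = sum(mp$sig_2_3),
    sig_conv_pair_1_2 = sum(conv$sig_1_2),
    sig_conv_pair_1_3 = sum(conv$sig_1_3),
    sig_conv_pair_2_3 = sum(conv$sig_2_3),
    occc_all_increased = sum(mp$occc_all > conv$occc_all),
    occc_upper_increased = sum(mp$occc_upper > conv$occc_upper),
    excellent_upper_map = sum(mp$stable_upper),
    excellent_upper_conventional = sum(conv$stable_upper),
    excellent_all_map = sum(mp$stable_all),
    excellent_all_conventional = sum(conv$stable_all))
  stopifnot(counts$sig_any_map >= max(counts$sig_map_pair_1_2,
                                      counts$sig_map_pair_1_3,
                                      counts$sig_map_pair_2_3),
            counts$sig_any_conventional >= max(counts$sig_conv_pair_1_2,
                                               counts$sig_conv_pair_1_3,
                                               counts$sig_conv_pair_2_3))
  counts
}

#' @export
print.stability_report <- function(x, ...) {
  ct <- x$counts
  dias <- x$config$voi_diameters
  cat("<stability_report> ", ct$n_features, " features, ",
      x$config$n_scans, " scans, VOIs ", paste(dias, collapse = "/"),
      " mm, blocks ", x$config$block_mm, " mm\n", sep = "")
  cat("  significant (any pair):  conventional ", ct$sig_any_conventional,
      ", map ", ct$sig_any_map, "\n", sep = "")
  cat("  map per pair (", dias[1], "-", dias[2], ", ", dias[1], "-", dias[3],
      ", ", dias[2], "-", dias[3], " mm): ", ct$sig_map_pair_1_2, ", ",
      ct$sig_map_pair_1_3, ", ", ct$sig_map_pair_2_3, "\n", sep = "")
  cat("  OCCC increased with maps: all sizes ", ct$occc_all_increased,
      ", upper pair ", ct$occc_upper_increased, "\n", sep = "")
  cat("  excellent OCCC (upper pair): map ", ct$excellent_upper_map,
      ", conventional ", ct$excellent_upper_conventional, "\n", sep = "")
  invisible(x)
}

#' Write a stability report to disk
#'
#' Writes per-feature statistics tables (one CSV per mode), the long-format
#' measurement table (one row per scan x VOI size x mode), a JSON summary
#' with the headline counts and provenance, and optionally per-feature
#' boxplot figures comparing the two modes.
#'
#' @param report a `stability_report`.
#' @param dir output directory (created if missing).
#' @param figures logical; when `TRUE`, write one PNG boxplot per entry of
#'   `figure_features`.
#' @param figure_features feature names to plot (default: the first three).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, figures = FALSE,
                         figure_features = NULL) {
  stopifnot(inherits(report, "stability_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- report$records
  utils::write.csv(rec[rec$mode == "conventional", ],
                   file.path(dir, "stability_conventional.csv"),
                   row.names = FALSE)
  utils::write.csv(rec[rec$mode == "map", ],
                   file.path(dir, "stability_map.csv"), row.names = FALSE)

  long <- do.call(rbind, lapply(names(report$tables), function(mode) {
    tb <- report$tables[[mode]]
    do.call(rbind, lapply(seq_len(dim(tb)[2]), function(j) {
      df <- as.data.frame(tb[, j, ])
      cbind(data.frame(scan = seq_len(nrow(df)),
                       voi_mm = report$config$voi_diameters[j],
                       mode = mode), df)
    }))
  }))
  utils::write.csv(long, file.path(dir, "measurements.csv"),
                   row.names = FALSE)

  jsonlite::write_json(list(counts = report$counts,
                            provenance = report$provenance,
                            alpha = report$config$alpha,
                            occc_cutoff = report$config$occc_cutoff,
                            voi_diameters = report$config$voi_diameters,
                            block_mm = report$config$block_mm),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (figures) {
    if (is.null(figure_features))
      figure_features <- utils::head(dimnames(report$tables[[1]])[[3]], 3)
    fdir <- file.path(dir, "figures")
    dir.create(fdir, showWarnings = FALSE)
    for (f in figure_features) {
      grDevices::png(file.path(fdir, paste0(f, ".png")),
                     width = 900, height = 450)
      graphics::par(mfrow = c(1, 2))
      for (mode in names(report$tables)) {
        graphics::boxplot(report$tables[[mode]][, , f],
                          names = paste0(report$config$voi_diameters, " mm"),
                          main = paste(f, "-", mode),
                          xlab = "VOI diameter", ylab = f)
      }
      grDevices::dev.off()
    }
  }
  invisible(dir)
}
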