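test_that("block grid tiles the volume with whole blocks only", {
  vol <- image_volume(array(0, c(96, 96, 96)))
  g <- plan_block_grid(vol, 4)
  expect_equal(g$n_blocks, c(24L, 24L, 24L))
  expect_equal(g$vpb, c(4L, 4L, 4L))
  expect_equal(g$map_origin, rep(1.5, 3))   # centre of the first 4^3 block

  # block equal to the full extent: exactly one block
  vol2 <- image_volume(array(0, c(8, 8, 8)))
  expect_equal(plan_block_grid(vol2, 8)$n_blocks, c(1L, 1L, 1L))

  # partial boundary blocks are dropped
  vol3 <- image_volume(array(0, c(10, 10, 10)))
  expect_equal(plan_block_grid(vol3, 4)$n_blocks, c(2L, 2L, 2L))

  # alignment shifts every block boundary rigidly
  ga <- plan_block_grid(vol, 4, alignment_mm = c(1, 1, 1))
  expect_equal(ga$map_origin, g$map_origin + 1)
  expect_equal(ga$n_blocks, c(23L, 23L, 23L))

  expect_error(plan_block_grid(image_volume(array(0, c(8, 8, 8)),
                                            spacing = c(3, 3, 3)), 4),
               "integer multiple")
  expect_error(plan_block_grid(vol2, 0.5), "smaller than one source voxel")
})

test_that("every map voxel equals direct extraction on its block", {
  set.seed(21)
  vol <- image_volume(array(rnorm(12^3, 5, 10), c(12, 12, 12)))
  grid <- plan_block_grid(vol, 4)
  maps <- compute_feature_maps(vol, grid)
  expect_length(maps$maps, 93)
  for (k in 1:3) for (j in 1:3) for (i in 1:3) {
    mask <- array(FALSE, c(12, 12, 12))
    mask[(i - 1) * 4 + 1:4, (j - 1) * 4 + 1:4, (k - 1) * 4 + 1:4] <- TRUE
    fv <- extract_features(vol, mask)
    for (f in names(maps$maps))
      expect_identical(maps$maps[[f]]$data[i, j, k], unname(fv[f]))
  }
})

test_that("map spatial metadata places voxels at block centres", {
  vol <- image_volume(array(0, c(12, 12, 12)), spacing = c(1, 1, 1),
                      origin = c(10, 20, 30))
  grid <- plan_block_grid(vol, 4)
  maps <- compute_feature_maps(vol, grid, features = "firstorder_Mean")
  m <- maps$maps[["firstorder_Mean"]]
  expect_equal(m$spacing, c(4, 4, 4))
  expect_equal(m$origin, c(11.5, 21.5, 31.5))
})

test_that("unknown feature names are rejected before computing", {
  vol <- image_volume(array(0, c(8, 8, 8)))
  grid <- plan_block_grid(vol, 4)
  expect_error(compute_feature_maps(vol, grid, features = "glcm_Bogus"),
               "unknown feature")
})

test_that("zero-noise phantom: constant mean map, edge blocks stand out", {
  g <- phantom_geometry(vol_dim = c(48, 48, 48), body_radius = 12,
                        body_height = 24, body_value = 5)
  scan <- generate_phantom_scan(g, noise_model(sigma = 0))
  grid <- plan_block_grid(scan, 4)
  maps <- compute_feature_maps(scan, grid,
                               features = c("firstorder_Mean",
                                            "firstorder_Variance"))
  mean_map <- maps$maps[["firstorder_Mean"]]$data
  var_map <- maps$maps[["firstorder_Variance"]]$data
  # interior blocks (well inside the 12 mm cylinder around block index 6,6,6)
  expect_true(all(mean_map[6:7, 6:7, 5:8] == 5))
  expect_true(all(var_map[6:7, 6:7, 5:8] == 0))
  # a block straddling the body edge mixes two intensities
  edge_idx <- which(var_map > 0, arr.ind = TRUE)
  expect_gt(nrow(edge_idx), 0)
  expect_gt(max(var_map), 0)
})

test_that("cropping to whole blocks preserves the block grid values", {
  set.seed(23)
  vol <- image_volume(array(rnorm(24^3), c(24, 24, 24)))
  full <- compute_feature_maps(vol, plan_block_grid(vol, 4),
                               features = "firstorder_Mean")
  crop <- crop_volume_blocks(vol, centre_mm = c(11.5, 11.5, 11.5),
                             half_width_mm = 6, block_mm = 4)
  cm <- compute_feature_maps(crop, plan_block_grid(crop, 4),
                             features = "firstorder_Mean")
  fm <- full$maps[[1]]; sm <- cm$maps[[1]]
  # locate the cropped sub-grid inside the full map by origin offset
  off <- as.integer(round((sm$origin - fm$origin) / 4))
  sub <- fm$data[off[1] + seq_len(dim(sm$data)[1]),
                 off[2] + seq_len(dim(sm$data)[2]),
                 off[3] + seq_len(dim(sm$data)[3])]
  expect_identical(sub, sm$data)
})

test_that("resampling enables block tiling for non-divisor spacings", {
  vol <- image_volume(array(rnorm(10 * 10 * 20), c(10, 10, 20)),
                      spacing = c(1.5, 1.5, 0.75))
  rs <- resample_for_blocks(vol, 4)
  expect_true(all(abs(4 / rs$spacing - round(4 / rs$spacing)) < 1e-9))
  g <- plan_block_grid(rs, 4)
  expect_true(all(g$n_blocks >= 1))
})

test_that("maps round-trip through disk bit-exactly", {
  set.seed(24)
  vol <- image_volume(array(rnorm(8^3), c(8, 8, 8)), origin = c(1, 2, 3))
  maps <- compute_feature_maps(vol, plan_block_grid(vol, 4),
                               features = c("firstorder_Mean", "glcm_Contrast",
                                            "ngtdm_Coarseness"))
  dir <- withr::local_tempdir()
  save_maps(maps, dir)
  back <- load_maps(dir)
  expect_identical(names(back$maps), names(maps$maps))
  for (f in names(maps$maps)) {
    expect_identical(back$maps[[f]]$data, maps$maps[[f]]$data)
    expect_equal(back$maps[[f]]$spacing, rep(4, 3))
    expect_equal(back$maps[[f]]$origin, maps$maps[[f]]$origin)
  }
  expect_equal(back$settings$bin_width, 25)

  # tampered manifest metadata is rejected
  man <- jsonlite::read_json(file.path(dir, "maps.json"), simplifyVector = TRUE)
  man$map_origin <- man$map_origin + 5
  jsonlite::write_json(man, file.path(dir, "maps.json"), auto_unbox = TRUE)
  expect_error(load_maps(dir), "spatial metadata")
})
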