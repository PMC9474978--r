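test_that("sphere mask voxel count tracks the analytic sphere volume", {
  vol <- image_volume(array(0, c(32, 32, 32)))
  ideal <- pi / 6 * 16^3
  for (ctr in list(c(16, 16, 16), c(15.5, 15.5, 15.5))) {
    m <- make_sphere_mask(vol, spherical_voi(ctr, 16))
    expect_equal(sum(m), ideal, tolerance = 0.02)
  }
  # halving the spacing multiplies the count by ~8
  fine <- image_volume(array(0, c(64, 64, 64)), spacing = c(0.5, 0.5, 0.5))
  m2 <- make_sphere_mask(fine, spherical_voi(c(16, 16, 16), 16))
  m1 <- make_sphere_mask(vol, spherical_voi(c(16, 16, 16), 16))
  expect_equal(sum(m2) / sum(m1), 8, tolerance = 0.02)
})

test_that("tiny sphere on a voxel centre hits exactly one voxel", {
  vol <- image_volume(array(0, c(9, 9, 9)))
  m <- make_sphere_mask(vol, spherical_voi(c(4, 4, 4), 0.5))
  expect_equal(sum(m), 1)
  expect_true(m[5, 5, 5])
})

test_that("mask voxel count is monotone in diameter", {
  vol <- image_volume(array(0, c(32, 32, 32)))
  counts <- vapply(c(4, 6, 8, 12, 16), function(d)
    sum(make_sphere_mask(vol, spherical_voi(c(15.5, 15.5, 15.5), d))), 0)
  expect_true(all(diff(counts) > 0))
})

test_that("VOIs outside the volume or below resolution are rejected", {
  vol <- image_volume(array(0, c(16, 16, 16)))
  expect_error(make_sphere_mask(vol, spherical_voi(c(2, 8, 8), 8)), "outside")
  expect_error(make_sphere_mask(vol, spherical_voi(c(7.5, 7.5, 7.3), 0.2)),
               "empty VOI mask")
})

test_that("conventional extraction shows the volume-confounding mechanism", {
  g <- phantom_geometry(vol_dim = c(48, 48, 48), body_radius = 12,
                        body_height = 24, body_value = 5)
  scan <- generate_phantom_scan(g, noise_model(sigma = 0))
  ctr <- body_centre(g)
  f8 <- conventional_extract(scan, spherical_voi(ctr, 8))
  f16 <- conventional_extract(scan, spherical_voi(ctr, 16))
  expect_length(f8, 93)
  n8 <- sum(make_sphere_mask(scan, spherical_voi(ctr, 8)))
  n16 <- sum(make_sphere_mask(scan, spherical_voi(ctr, 16)))
  # zero noise: mean invariant, energy scales exactly with voxel count
  expect_equal(unname(f16["firstorder_Mean"]), unname(f8["firstorder_Mean"]))
  expect_equal(unname(f16["firstorder_Energy"] / f8["firstorder_Energy"]),
               n16 / n8)
  # purity: identical scan + VOI give identical vectors
  expect_identical(f8, conventional_extract(scan, spherical_voi(ctr, 8)))
})

test_that("map readout is the mean over in-sphere map voxels", {
  # 3x3x3-block fixture with known values
  set.seed(41)
  vol <- image_volume(array(rnorm(12^3), c(12, 12, 12)))
  maps <- compute_feature_maps(vol, plan_block_grid(vol, 4),
                               features = "firstorder_Mean")
  m <- maps$maps[[1]]
  # block centres at 1.5, 5.5, 9.5 per axis; VOI at the middle block centre
  ctr <- c(5.5, 5.5, 5.5)
  # d = 4: only the central block centre is inside
  r1 <- map_readout(maps, spherical_voi(ctr, 4))
  expect_equal(unname(r1[1]), m$data[2, 2, 2])
  expect_false(attr(r1, "fallback_nearest"))
  # d = 9: centre plus the 6 face neighbours (distance 4 < 4.5)
  r2 <- map_readout(maps, spherical_voi(ctr, 9))
  idx <- rbind(c(2, 2, 2), c(1, 2, 2), c(3, 2, 2), c(2, 1, 2), c(2, 3, 2),
               c(2, 2, 1), c(2, 2, 3))
  expect_equal(unname(r2[1]), mean(m$data[idx]))
  # readout is order-invariant by construction: same VOI, same value
  expect_equal(unname(map_readout(maps, spherical_voi(ctr, 9))[1]),
               unname(r2[1]))
})

test_that("readout falls back to the nearest map voxel and flags it", {
  vol <- image_volume(array(5, c(12, 12, 12)))
  maps <- compute_feature_maps(vol, plan_block_grid(vol, 4),
                               features = "firstorder_Mean")
  r <- map_readout(maps, spherical_voi(c(3.4, 5.5, 5.5), 1))
  expect_true(attr(r, "fallback_nearest"))
  expect_equal(unname(r[1]), 5)
})

test_that("constant map reads the constant for every diameter", {
  vol <- image_volume(array(5, c(16, 16, 16)))
  maps <- compute_feature_maps(vol, plan_block_grid(vol, 4),
                               features = "firstorder_Mean")
  for (d in c(4, 8, 12))
    expect_equal(unname(map_readout(maps, spherical_voi(c(7.5, 7.5, 7.5), d))[1]), 5)
})

test_that("cube-in-sphere fraction: closed forms and Monte Carlo agreement", {
  expect_equal(central_voxel_fraction(8, 4), 4^3 / (pi / 6 * 8^3))
  expect_equal(central_voxel_fraction(16, 4), 4^3 / (pi / 6 * 16^3))
  expect_equal(central_voxel_fraction(4, 4), 1)
  # intermediate regime: compare the seeded Monte Carlo against a fine
  # lattice quadrature of the cube-sphere intersection
  d <- 5; b <- 4
  h <- 0.02
  gr <- seq(-d / 2 + h / 2, d / 2 - h / 2, by = h)
  inside_sphere <- outer(outer(gr^2, gr^2, "+"), gr^2, "+") <= (d / 2)^2
  in_cube <- abs(gr) <= b / 2
  inter <- sum(inside_sphere & outer(outer(in_cube, in_cube, "&"), in_cube, "&")) * h^3
  lattice <- inter / (pi / 6 * d^3)
  mc <- central_voxel_fraction(5, 4, n_points = 2e6)
  expect_equal(mc, lattice, tolerance = 2e-3)
  # Monte Carlo is seeded: repeated calls agree exactly
  expect_identical(mc, central_voxel_fraction(5, 4, n_points = 2e6))
})
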