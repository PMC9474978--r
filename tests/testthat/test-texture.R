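# Texture-matrix features against brute-force enumeration oracles and
# hand-worked examples. `disc_of` builds the discretization object the
# feature functions consume directly from a level grid.

disc_of <- function(lev) list(levels = lev, n_levels = max(lev, na.rm = TRUE),
                              min_value = 0)

test_that("all five texture classes match enumeration oracles on random grids", {
  set.seed(101)
  for (r in 1:40) {
    g <- random_level_grid(c(4, 4, 4), ng = sample(2:5, 1),
                           mask_frac = if (r > 25) 0.3 else 0)
    d <- disc_of(g$levels)
    expect_equal(glcm_features(d), o_glcm_features(g$levels, g$n_levels),
                 tolerance = 1e-10)
    expect_equal(glrlm_features(d), o_glrlm_features(g$levels, g$n_levels),
                 tolerance = 1e-10)
    expect_equal(glszm_features(d), o_glszm_features(g$levels, g$n_levels),
                 tolerance = 1e-10)
    expect_equal(gldm_features(d), o_gldm_features(g$levels, g$n_levels),
                 tolerance = 1e-10)
    expect_equal(ngtdm_features(d), o_ngtdm_features(g$levels, g$n_levels),
                 tolerance = 1e-10)
  }
})

test_that("GLCM: constant region and toy grids", {
  lev <- array(1L, c(2, 2, 2))
  f <- glcm_features(disc_of(lev))
  expect_equal(unname(f["glcm_Contrast"]), 0)
  expect_equal(unname(f["glcm_JointEntropy"]), 0)
  expect_equal(unname(f["glcm_Correlation"]), 1)   # zero-variance definition
  expect_equal(unname(f["glcm_MCC"]), 1)

  toy <- array(c(1L, 2L, 3L, 2L, 1L, 2L, 3L, 2L, 1L), c(3, 3, 1))
  expect_equal(glcm_features(disc_of(toy)), o_glcm_features(toy, 3L),
               tolerance = 1e-12)

  # cluster shade vanishes for a grey-level-symmetric pattern
  strip <- array(rep(c(1L, 2L), 8), c(16, 1, 1))
  f <- glcm_features(disc_of(strip))
  expect_equal(unname(f["glcm_ClusterShade"]), 0, tolerance = 1e-12)

  expect_error(glcm_features(disc_of(array(1L, c(1, 1, 1)))), "degenerate")
})

test_that("GLRLM: hand-enumerated runs", {
  # constant 4x4x4 region, direction (1,0,0): 16 runs of length 4
  lev <- array(1L, c(4, 4, 4))
  P <- radiomaps:::glrlm_matrix(lev, 1L, c(1L, 0L, 0L))
  expect_equal(ncol(P), 4)
  expect_equal(P[1, 4], 16)
  expect_equal(sum(P), 16)
  expect_equal(sum(P) / 64, 0.25)                  # run percentage, this direction

  # alternating strip: all runs length 1, long run emphasis 1
  strip <- array(rep(c(1L, 2L), 8), c(16, 1, 1))
  f <- glrlm_features(disc_of(strip))
  expect_equal(unname(f["glrlm_LongRunEmphasis"]), 1)
  expect_equal(unname(f["glrlm_ShortRunEmphasis"]), 1)

  # runs break at mask boundaries
  lev <- array(1L, c(6, 1, 1))
  lev[3] <- NA
  P <- radiomaps:::glrlm_matrix(lev, 1L, c(1L, 0L, 0L))
  expect_equal(P[1, 2], 1)   # run of 2 before the gap
  expect_equal(P[1, 3], 1)   # run of 3 after it
})

test_that("GLSZM: single zones and disjoint blobs", {
  lev <- array(2L, c(3, 3, 3)); lev[1, 1, 1] <- 1L   # level range 1..2
  f <- glszm_features(disc_of(lev))
  # two zones: sizes 1 (level 1) and 26 (level 2)
  expect_equal(unname(f["glszm_SmallAreaEmphasis"]), (1 + 1 / 26^2) / 2)

  one <- array(1L, c(2, 2, 2))
  f <- glszm_features(disc_of(one))
  expect_equal(unname(f["glszm_SmallAreaEmphasis"]), 1 / 64)   # 1/N^2, N = 8
  expect_equal(unname(f["glszm_ZoneEntropy"]), 0)

  # blobs of sizes 2 and 3 with the same level, separated by another level
  lev <- array(c(1L, 1L, 4L, 1L, 1L, 1L), c(6, 1, 1))
  z <- radiomaps:::glszm_zones(lev)
  z1 <- z[z$level == 1, ]
  expect_setequal(z1$size, c(2, 3))
  expect_equal(nrow(z1), 2)
})

test_that("GLDM: neighbour counts and single-voxel dependence", {
  lev <- array(1L, c(3, 3, 3))
  P <- radiomaps:::gldm_matrix(lev, 1L)
  expect_equal(P[1, 27], 1)       # centre voxel: dependence 26 -> column 27
  expect_equal(sum(P), 27)        # every voxel contributes once

  single <- array(1L, c(1, 1, 1))
  P <- radiomaps:::gldm_matrix(single, 1L)
  expect_equal(dim(P), c(1L, 1L)) # dependence-0 column only
  expect_equal(P[1, 1], 1)
})

test_that("NGTDM: constant region and hand-worked bright-centre grid", {
  f <- ngtdm_features(disc_of(array(1L, c(3, 3, 3))))
  expect_equal(unname(f["ngtdm_Busyness"]), 0)
  expect_equal(unname(f["ngtdm_Contrast"]), 0)
  expect_equal(unname(f["ngtdm_Coarseness"]), 1e6)  # capped degenerate value

  lev <- array(1L, c(3, 3, 1)); lev[2, 2, 1] <- 2L
  st <- radiomaps:::ngtdm_summaries(lev, 2L)
  expect_equal(st$s_i, c(4 / 3 + 4 / 5, 1))  # corners 4*(1/3), edges 4*(1/5); centre 1
  expect_equal(st$n_i, c(8, 1))
})

test_that("texture features are translation invariant through discretization", {
  set.seed(55)
  v <- array(rnorm(6^3, 0, 30), c(6, 6, 6))
  mask <- array(TRUE, c(6, 6, 6))
  s <- extraction_settings()
  a <- extract_features(image_volume(v), mask, s)
  b <- extract_features(image_volume(v + 250), mask, s)
  tex <- grep("^(glcm|gldm|glrlm|glszm|ngtdm)_", names(a), value = TRUE)
  expect_equal(a[tex], b[tex], tolerance = 1e-12)
  # location features shift by exactly k
  for (nm in c("firstorder_Mean", "firstorder_Median", "firstorder_Minimum",
               "firstorder_Maximum", "firstorder_10Percentile",
               "firstorder_90Percentile"))
    expect_equal(unname(b[nm] - a[nm]), 250)
})
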