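test_that("curve construction enforces its invariants", {
  expect_error(ioert_curve(c(1, 3, 2), c(1, 2, 3)), "increasing")
  expect_error(ioert_curve(1:3, 1:3, sigma = -1))
  cv <- ioert_curve(1:5, 5:1, axis = "inplane")
  expect_s3_class(cv, "ioert_curve")
  expect_s3_class(cv, "tbl_df")
})

test_that("scoring-volume averages equal a brute-force voxel loop", {
  g <- fixture_run(9, n = 2e4, seed = 11)
  sc <- scoring_pdd()
  pdd <- extract_pdd(g, sc)
  # independent oracle: explicit loop over covered voxels
  xc <- grid_axis(g, 1); yc <- grid_axis(g, 2)
  # half-open footprint convention, like the voxel grid itself
  ix <- which(xc >= -sc$lateral / 2 - 1e-9 & xc < sc$lateral / 2 - 1e-9)
  iy <- which(yc >= -sc$depth / 2 - 1e-9 & yc < sc$depth / 2 - 1e-9)
  for (iz in c(1, 10, 25, 60)) {
    acc <- 0
    for (i in ix) for (j in iy) acc <- acc + g$energy[i, j, iz]
    expect_equal(pdd$value[iz], acc / (length(ix) * length(iy)))
  }
  prof <- extract_profile(g, 15, "inplane", scoring_profile())
  lat <- scoring_profile()$lateral / 2
  dep <- scoring_profile()$depth / 2
  iy2 <- which(yc >= -lat - 1e-9 & yc < lat - 1e-9)
  zc <- grid_axis(g, 3)
  iz2 <- which(zc >= 15 - dep - 1e-9 & zc < 15 + dep - 1e-9)
  for (i in c(20, 80, 140)) {
    acc <- 0
    for (j in iy2) for (k in iz2) acc <- acc + g$energy[i, j, k]
    expect_equal(prof$value[i], acc / (length(iy2) * length(iz2)))
  }
})

test_that("uniform grids give flat curves and mirrored grids mirror profiles", {
  g <- fixture_run(9, n = 2e4, seed = 11)
  gu <- g
  gu$energy <- array(1.5, dim = g$dims)
  gu$entries <- array(100L, dim = g$dims)
  expect_true(all(extract_pdd(gu)$value == 1.5))
  gm <- g
  gm$energy <- g$energy[rev(seq_len(g$dims[1])), , ]
  gm$entries <- g$entries[rev(seq_len(g$dims[1])), , ]
  p <- extract_profile(g, 15, "inplane", scoring_volume(1, 3, 1))
  pm <- extract_profile(gm, 15, "inplane", scoring_volume(1, 3, 1))
  expect_equal(pm$value, rev(p$value))
})

test_that("extraction rejects footprints and depths outside the grid", {
  g <- fixture_run(9, n = 2e4, seed = 11)
  expect_error(extract_pdd(g, scoring_volume(1, 1000, 6)), "exceeds")
  expect_error(extract_profile(g, 500, "inplane"), "outside")
})

test_that("find_zmax takes the first maximum and supports smoothing", {
  cv <- fixture_pdd_curve(zmax = 18, r50 = 36)
  expect_equal(find_zmax(cv), 18)
  # plateau of equal maxima: tie broken toward the smaller depth
  plateau <- ioert_curve(seq(0, 30), c(seq(0, 11), 100, 100, rep(10, 17)))
  expect_equal(find_zmax(plateau), 12)
  # all-zero curve is an error
  expect_error(find_zmax(ioert_curve(1:5, rep(0, 5))), "maximum")
  # smoothed argmax equals an exhaustive scan of the smoothed curve
  set.seed(4)
  noisy <- ioert_curve(seq(0, 60), pmax(0, 100 - (seq(0, 60) - 20)^2 / 10 +
                                          rnorm(61, 0, 3)))
  v <- noisy$value
  for (k in 1:3) v <- ioertmc:::smooth3(v)
  expect_equal(find_zmax(noisy, smoothing_passes = 3),
               noisy$position_mm[which.max(v)])
})

test_that("normalized PDD has maximum exactly 100", {
  g <- fixture_run(9, n = 2e4, seed = 11)
  np <- normalize_curve(extract_pdd(g))
  expect_equal(max(np$value), 100)
  # normalizing at an explicit position records the reference
  np2 <- normalize_curve(extract_pdd(g), at_position = 18)
  expect_equal(attr(np2, "normalization")$position, 18)
})

test_that("measurement resampling reproduces the documented grids and is linear-exact", {
  # output positions match an independently constructed grid
  prof <- ioert_curve(seq(-80, 80, by = 0.5), rep(1, 321), axis = "inplane")
  rs <- resample_to_measurement(prof, field_diameter_mm = 100)
  half_flat <- ceiling(0.35 * 100)
  expected <- sort(unique(c(seq(-80, -half_flat, by = 1),
                            seq(-half_flat, half_flat, by = 2),
                            seq(half_flat, 80, by = 1))))
  expect_equal(rs$position_mm, expected)
  expect_true(all(rs$value == 1))           # constant stays constant
  # linear ramp survives the 4 mm -> 2 mm interpolation exactly
  ramp <- ioert_curve(seq(-80, 80, by = 0.5), seq(-80, 80, by = 0.5) * 2 + 5,
                      axis = "inplane")
  rr <- resample_to_measurement(ramp, field_diameter_mm = 100)
  expect_equal(rr$value, rr$position_mm * 2 + 5)
  # depth curves: 1 mm through build-up, 2 mm beyond
  pdd <- ioert_curve(seq(0, 60, by = 0.5), rep(1, 121))
  rp <- resample_to_measurement(pdd, zmax_mm = 18)
  expect_equal(rp$position_mm, c(seq(0, 18, 1), seq(20, 60, 2)))
})

test_that("profile FWHM matches the collimated field size", {
  g <- fixture_run(9, n = 2e5, seed = 42)
  prof <- extract_profile(g, 15, "inplane")
  expect_equal(curve_fwhm(prof), 100, tolerance = 0.1) # 10 +- 1 cm
})
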