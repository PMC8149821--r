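test_that("drift correction recovers applied drift and is near-null otherwise", {
  # zero applied drift: shifts within half a correlation pixel
  still <- cluster_scene(6000, drift_per_frame = c(0, 0), seed = 3)
  dc0 <- drift_correct_xy(still, block_frames = 2000, corr_pixel = 0.05)
  expect_true(all(abs(dc0$drift$dx_um) <= 0.025 + 1e-9))
  expect_true(all(abs(dc0$drift$dy_um) <= 0.025 + 1e-9))

  # applied linear drift of 2 nm/frame in x: trace recovered within 10%
  drifting <- cluster_scene(6000, drift_per_frame = c(0.002, 0), seed = 4)
  dc <- drift_correct_xy(drifting, block_frames = 2000, corr_pixel = 0.05)
  expected <- (dc$drift$frame_center - dc$drift$frame_center[1]) * 0.002
  expect_equal(dc$drift$dx_um[-1], expected[-1], tolerance = 0.1)
  # corrected table: residual drift removed (compare first/last block means)
  first <- dc$table$x_um[dc$table$frame < 2000]
  last <- dc$table$x_um[dc$table$frame >= 4000]
  expect_lt(abs(mean(last) - mean(first)), 0.3)
  # z untouched
  expect_identical(dc$table$z_nm, drifting$z_nm)

  # single block: identity transform
  one <- cluster_scene(1000, seed = 5)
  dc1 <- drift_correct_xy(one, block_frames = 2000)
  expect_identical(dc1$table$x_um, one$x_um)
  expect_equal(dc1$drift$dx_um, 0)
})

test_that("mean-z maps average per pixel, honour the 150 nm display cut", {
  mask <- tiny_mask()
  uni <- localization_table(data.frame(
    track_id = sprintf("u%d", 1:500), frame = 0:499,
    x_um = runif(500, 1.5, 8.5), y_um = runif(500, 1.5, 8.5), z_nm = 50))
  mz <- render_mean_z(uni, mask, render_pixel = 0.5)
  expect_true(all(abs(mz[!is.na(mz)] - 50) < 1e-9))

  # two equal-count populations at 40 and 80 nm in the same pixel -> 60
  two <- localization_table(data.frame(
    track_id = sprintf("t%d", 1:10), frame = 0:9,
    x_um = 3.1, y_um = 3.1, z_nm = rep(c(40, 80), 5)))
  mz2 <- render_mean_z(two, mask, render_pixel = 0.5, kernel = 1)
  expect_equal(mz2[!is.na(mz2)], 60)

  # a molecule above the cut is absent
  hi <- localization_table(data.frame(track_id = c("a", "b"), frame = 0:1,
                                      x_um = c(3.1, 6.1), y_um = 3.1,
                                      z_nm = c(160, 50)))
  mz3 <- render_mean_z(hi, mask, render_pixel = 0.5, kernel = 1)
  expect_identical(sum(!is.na(mz3)), 1L)
  expect_equal(mz3[!is.na(mz3)], 50)
})

test_that("z profiles find the dominant peak and conserve counts", {
  mask <- tiny_mask()
  # delta distribution
  delta <- localization_table(data.frame(
    track_id = sprintf("d%d", 1:200), frame = 0:199,
    x_um = runif(200, 1.5, 8.5), y_um = runif(200, 1.5, 8.5), z_nm = 66.3))
  pr <- suppressWarnings(z_profile(delta, mask))
  expect_equal(pr$outside_fa$z_peak, 66.3, tolerance = 5 / 66.3)

  # synthetic Gaussian cloud: z_peak within 1 nm on 1e4 points
  big_mask <- simulate_mask_set(n_fa = 1)
  cloud <- simulate_axial_cloud(48.7, 30, 1e4, big_mask, seed = 6)
  pr2 <- suppressWarnings(z_profile(cloud, big_mask))
  expect_equal(pr2$outside_fa$z_peak, 48.7, tolerance = 1 / 48.7)
  expect_false(pr2$outside_fa$low_confidence)

  # counts conserved: sum over bins = localizations in the region
  px <- loc_to_pixel(cloud$x_um, cloud$y_um, big_mask)
  in_cell <- sptfa:::mask_value_at(big_mask$cell_mask, px$ix, px$iy,
                                   outside = FALSE)
  in_fa <- sptfa:::mask_value_at(big_mask$fa_labels, px$ix, px$iy) > 0
  expect_identical(sum(pr2$outside_fa$counts), sum(in_cell & !in_fa))

  # bimodal 40/140 nm at 60/40 weights: the dominant mode is fitted
  set.seed(8)
  bi <- localization_table(data.frame(
    track_id = sprintf("b%d", 1:5000), frame = 0:4999,
    x_um = runif(5000, 2, 18), y_um = runif(5000, 2, 18),
    z_nm = c(rnorm(3000, 40, 10), rnorm(2000, 140, 10))))
  pr3 <- suppressWarnings(z_profile(bi, big_mask))
  expect_equal(pr3$outside_fa$z_peak, 40, tolerance = 5 / 40)

  # box stats are computed on the z <= 200 nm subset only
  expect_lte(pr3$outside_fa$box_stats[["q75"]], 200)
  expect_equal(pr3$outside_fa$box_stats[["median"]],
               median(bi$z_nm[bi$z_nm <= 200]), tolerance = 0.05)

  # regions below 100 localizations are flagged
  tiny <- localization_table(data.frame(
    track_id = sprintf("s%d", 1:40), frame = 0:39,
    x_um = runif(40, 1.5, 8.5), y_um = runif(40, 1.5, 8.5), z_nm = 66.3))
  small <- suppressWarnings(z_profile(tiny, mask))
  expect_true(small$outside_fa$low_confidence)
})

test_that("z_peak recovery bias stays below half a bin across the range", {
  big_mask <- simulate_mask_set(n_fa = 1)
  for (zc in c(30, 60, 100)) {
    cloud <- simulate_axial_cloud(zc, 25, 1e4, big_mask, seed = zc)
    pr <- suppressWarnings(z_profile(cloud, big_mask))
    expect_lt(abs(pr$outside_fa$z_peak - zc), 5)
  }
})
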