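test_that("sim_config validates its invariants", {
  expect_error(sim_config(mode_proportions = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_config(frame_interval = 0))
  expect_error(sim_config(D_free = -1))
  expect_error(sim_config(pointing_accuracy = -0.01))
})

test_that("zero-noise immobile trajectories sit exactly at the origin", {
  cfg <- sim_config(pointing_accuracy = 0, blink_off_prob = 0, n_frames = 20)
  tr <- simulate_trajectory("immobile", cfg, origin = c(2.5, -1), seed = 4)
  expect_true(all(tr$x == 2.5) && all(tr$y == -1))
})

test_that("free-mode increments are Gaussian with variance 2 D dt", {
  cfg <- sim_config(n_frames = 10001, pointing_accuracy = 0,
                    blink_off_prob = 0, D_free = 0.2)
  tr <- simulate_trajectory("free", cfg, seed = 11)
  inc <- c(diff(tr$x), diff(tr$y))
  n <- length(inc)
  v_target <- 2 * 0.2 * 0.02
  se_var <- v_target * sqrt(2 / (n - 1))
  expect_lt(abs(var(inc) - v_target), 3 * se_var)
  # moment-based normality check at alpha = 0.001
  z <- scale(inc)[, 1]
  skew_z <- mean(z^3) * sqrt(n / 6)
  kurt_z <- (mean(z^4) - 3) * sqrt(n / 24)
  expect_lt(abs(skew_z), 3.29)
  expect_lt(abs(kurt_z), 3.29)
})

test_that("ensemble free MSD recovers D within 5%", {
  cfg <- sim_config(n_frames = 100, pointing_accuracy = 0,
                    blink_off_prob = 0, D_free = 0.2)
  Dh <- vapply(1:400, function(s) {
    tr <- simulate_trajectory("free", cfg, seed = s)
    estimate_D(compute_msd(tr))[["D"]]
  }, numeric(1))
  expect_equal(mean(Dh), 0.2, tolerance = 0.05)
})

test_that("confined positions never exceed the disc radius before noise", {
  cfg <- sim_config(n_frames = 500, pointing_accuracy = 0,
                    blink_off_prob = 0, disc_radius = 0.2, D_conf = 0.3)
  for (s in 1:5) {
    tr <- simulate_trajectory("confined", cfg, origin = c(1, 1), seed = s)
    expect_lte(max(sqrt((tr$x - 1)^2 + (tr$y - 1)^2)), 0.2 + 1e-12)
  }
})

test_that("long confined trajectories plateau at R^2", {
  cfg <- sim_config(n_frames = 3000, pointing_accuracy = 0,
                    blink_off_prob = 0, disc_radius = 0.2, D_conf = 0.1)
  plateau <- vapply(1:4, function(s) {
    tr <- simulate_trajectory("confined", cfg, seed = s)
    m <- compute_msd(tr)
    mean(m$values[m$lag_frames >= 50 & m$lag_frames <= 300])
  }, numeric(1))
  expect_equal(mean(plateau), 0.2^2, tolerance = 0.1)
})

test_that("simulate_dataset is deterministic and mixes modes as configured", {
  mask <- tiny_mask()
  cfg <- sim_config(rng_seed = 42L, n_frames = 15)
  ds1 <- simulate_dataset(cfg, mask, n_tracks = 50)
  ds2 <- simulate_dataset(cfg, mask, n_tracks = 50)
  expect_identical(ds1$table, ds2$table)
  expect_identical(ds1$labels, ds2$labels)
  expect_identical(length(unique(ds1$table$track_id)), 50L)
  expect_identical(nrow(ds1$labels), 50L)

  degenerate <- sim_config(mode_proportions = c(1, 0, 0), n_frames = 10)
  ds3 <- simulate_dataset(degenerate, mask, n_tracks = 30)
  expect_true(all(ds3$labels$true_mode == "immobile"))

  # 300 tracks at (1/3, 1/3, 1/3): counts inside the exact binomial 99% CI
  ds4 <- simulate_dataset(sim_config(rng_seed = 7L, n_frames = 10), mask,
                          n_tracks = 300)
  ci <- qbinom(c(0.005, 0.995), 300, 1 / 3)
  counts <- table(factor(ds4$labels$true_mode,
                         levels = c("immobile", "confined", "free")))
  expect_true(all(counts >= ci[1] & counts <= ci[2]))
})

test_that("blink gaps never exceed max_gap and endpoints stay on", {
  cfg <- sim_config(n_frames = 200, blink_off_prob = 0.2, max_gap = 2)
  for (s in 1:10) {
    tr <- simulate_trajectory("free", cfg, seed = s)
    expect_lte(max(diff(tr$frames)), cfg$max_gap + 1L)
    expect_identical(tr$frames[1], 0L)
    expect_identical(tr$frames[length(tr$frames)], cfg$n_frames - 1L)
  }
})

test_that("intensity pairs encode the membrane fraction on the assay scale", {
  mask <- simulate_mask_set(c(10, 10), pixel_size = 0.2, n_fa = 2)
  p1 <- simulate_intensity_pair(1, mask = mask)
  m1 <- membrane_fraction(p1$tirf, p1$epi, mask$cell_mask, p1$bg_rois)
  expect_equal(m1$f_membrane, 1)
  p5 <- simulate_intensity_pair(0.5, mask = mask)
  m5 <- membrane_fraction(p5$tirf, p5$epi, mask$cell_mask, p5$bg_rois)
  expect_equal(m5$f_membrane, 0.5)
  expect_error(simulate_intensity_pair(1.2), "membrane_fraction_true")

  # Poisson replicates: mean recovery within 0.05
  rec <- vapply(1:20, function(s) {
    p <- simulate_intensity_pair(0.5, mask = mask, seed = s,
                                 noise = "poisson")
    membrane_fraction(p$tirf, p$epi, mask$cell_mask, p$bg_rois)$f_membrane
  }, numeric(1))
  expect_equal(mean(rec), 0.5, tolerance = 0.05 / 0.5)
})

test_that("axial clouds honour their parameters", {
  mask <- tiny_mask()
  c0 <- simulate_axial_cloud(48.7, 0, 100, mask, seed = 1)
  expect_true(all(c0$z_nm == 48.7))
  expect_error(simulate_axial_cloud(50, 10, 0, mask), "n must be > 0")
  cg <- simulate_axial_cloud(30, 25, 5000, mask, seed = 2)
  expect_true(all(cg$z_nm >= 0))
  cg2 <- simulate_axial_cloud(30, 25, 5000, mask, seed = 2)
  expect_identical(cg, cg2)
})

test_that("masks are valid, FA pixels sit inside the cell", {
  mask <- simulate_mask_set(c(15, 15), pixel_size = 0.1, n_fa = 5, seed = 3)
  expect_s3_class(mask, "sptfa_mask_set")
  expect_true(all(mask$cell_mask[mask$fa_labels > 0]))
  expect_identical(sort(setdiff(unique(as.vector(mask$fa_labels)), 0L)), 1:5)
})
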