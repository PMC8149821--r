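test_that("compute_msd matches the hand example and the brute-force oracle", {
  tr <- trajectory("line", 0:3, c(0, 1, 2, 3), rep(0, 4))
  m <- compute_msd(tr)
  expect_equal(m$values, c(1, 4, 9))
  expect_equal(m$lags, c(0.02, 0.04, 0.06))
  expect_equal(m$pair_counts, c(3L, 2L, 1L))

  still <- trajectory("still", 0:9, rep(0.3, 10), rep(-0.1, 10))
  expect_true(all(compute_msd(still)$values == 0))

  for (seed in 1:30) {
    tr <- random_gapped_track(seed)
    m <- compute_msd(tr)
    oracle <- brute_msd(tr$frames, tr$x, tr$y)
    keep <- oracle$counts > 0
    expect_equal(m$values, oracle$values[keep])
    expect_equal(m$pair_counts, oracle$counts[keep])
  }
})

test_that("MSD lags are frame-index differences, gap-aware", {
  tr <- trajectory("gap", c(0, 1, 3), c(0, 1, 3), c(0, 0, 0))
  m <- compute_msd(tr)
  # lag 1: only the (0,1) pair; lag 2: only (1,3); lag 3: (0,3)
  expect_equal(m$lag_frames, c(1L, 2L, 3L))
  expect_equal(m$values, c(1, 4, 9))
  expect_equal(m$pair_counts, c(1L, 1L, 1L))
})

test_that("estimate_D reproduces hand OLS and rejects short curves", {
  msd <- msd_curve(1:4, c(0.008, 0.016, 0.024, 0.032), 4:1, 0.02)
  d <- estimate_D(msd)
  expect_equal(unname(d["slope"]), 0.4, tolerance = 1e-12)
  expect_equal(unname(d["D"]), 0.1, tolerance = 1e-12)

  flat <- msd_curve(1:4, rep(4 * 0.025^2, 4), 4:1, 0.02)
  expect_equal(unname(estimate_D(flat)["D"]), 0)

  short <- msd_curve(1:3, c(1, 4, 9), 3:1, 0.02)
  expect_error(estimate_D(short), "lags 1..4")

  # negative slopes pass through unclamped
  dec <- msd_curve(1:4, c(0.04, 0.03, 0.02, 0.01), 4:1, 0.02)
  expect_lt(unname(estimate_D(dec)["D"]), 0)
})

test_that("immobile threshold matches its defining formula and is monotone", {
  expect_equal(immobile_threshold(classifier_config()),
               0.059^2 / (4 * 4 * 0.02))
  expect_equal(round(immobile_threshold(classifier_config()), 3), 0.011)
  expect_equal(immobile_threshold(classifier_config(resolution_fwhm = 0)), 0)
  expect_equal(immobile_threshold(classifier_config(resolution_fwhm = 0.118)),
               0.118^2 / (4 * 4 * 0.02))
  expect_equal(round(immobile_threshold(classifier_config(resolution_fwhm = 0.118)), 4),
               0.0435)
  fwhms <- seq(0.02, 0.2, by = 0.02)
  thr_f <- vapply(fwhms, function(f)
    immobile_threshold(classifier_config(resolution_fwhm = f)), numeric(1))
  expect_true(all(diff(thr_f) > 0))
  dts <- seq(0.005, 0.1, by = 0.005)
  thr_t <- vapply(dts, function(dt)
    immobile_threshold(classifier_config(frame_interval = dt)), numeric(1))
  expect_true(all(diff(thr_t) < 0))
})

test_that("confinement fit recovers noiseless model parameters exactly", {
  cfg <- classifier_config()
  t <- (1:25) * 0.02
  for (p in list(c(0.1, 0.05), c(0.2, 0.02), c(0.05, 0.09))) {
    v <- (4 * p[1]^2 / 3) * (1 - exp(-t / p[2]))
    fit <- fit_confinement(msd_curve(1:25, v, 25:1, 0.02), cfg)
    expect_equal(fit$r_conf, p[1], tolerance = 1e-6)
    expect_equal(fit$tau, p[2], tolerance = 1e-6)
    expect_equal(fit$D_conf, p[1]^2 / (3 * p[2]), tolerance = 1e-5)
    expect_true(fit$fit_ok)
  }
})

test_that("linear (free) MSD drives tau above the confinement split", {
  cfg <- classifier_config()
  t <- (1:25) * 0.02
  fit <- suppressWarnings(
    fit_confinement(msd_curve(1:25, 4 * 0.2 * t, 25:1, 0.02), cfg))
  expect_gt(fit$tau, cfg$tau_threshold)
})

test_that("disc-confined simulations land on the 4 r_conf^2 / 3 plateau", {
  cfg <- sim_config(n_frames = 1500, pointing_accuracy = 0,
                    blink_off_prob = 0, disc_radius = 0.2, D_conf = 0.1)
  rc <- vapply(1:6, function(s) {
    tr <- simulate_trajectory("confined", cfg, seed = s)
    suppressWarnings(fit_confinement(compute_msd(tr), classifier_config()))$r_conf
  }, numeric(1))
  # plateau oracle: E|p1 - p2|^2 = R^2 for uniform points in a disc,
  # so 4 r_conf^2 / 3 = R^2 and r_conf = (sqrt(3)/2) R
  expect_equal(mean(rc), sqrt(3) / 2 * 0.2, tolerance = 0.1)
})

test_that("classification applies the track filter and decision tree", {
  cfg_sim <- sim_config(n_frames = 12, blink_off_prob = 0)
  tr12 <- simulate_trajectory("immobile", cfg_sim, seed = 1)
  expect_identical(classify(tr12)$mode, "excluded")
  cfg_sim$n_frames <- 13L
  tr13 <- simulate_trajectory("immobile", cfg_sim, seed = 1)
  expect_true(classify(tr13)$mode %in% c("immobile", "confined", "free"))
})

test_that("a trajectory classified immobile never has D >= threshold", {
  cfg <- classifier_config()
  thr <- immobile_threshold(cfg)
  for (seed in 1:40) {
    md <- c("immobile", "confined", "free")[seed %% 3 + 1]
    tr <- simulate_trajectory(md, sim_config(n_frames = 30), seed = seed)
    cl <- suppressWarnings(classify(tr, cfg))
    if (cl$mode == "immobile") expect_lt(cl$D, thr)
    if (cl$mode %in% c("confined", "free")) {
      expect_gte(cl$D, thr)
      expect_false(is.na(cl$tau))
    }
  }
})

test_that("classification is invariant to global translation and rotation", {
  cfg <- classifier_config()
  for (seed in 1:8) {
    md <- c("immobile", "confined", "free")[seed %% 3 + 1]
    tr <- simulate_trajectory(md, sim_config(n_frames = 40), seed = seed)
    ref <- suppressWarnings(classify(tr, cfg))
    shifted <- trajectory(tr$id, tr$frames, tr$x + 11.3, tr$y - 4.2,
                          frame_interval = tr$frame_interval)
    th <- 0.7
    rotated <- trajectory(tr$id, tr$frames,
                          cos(th) * tr$x - sin(th) * tr$y,
                          sin(th) * tr$x + cos(th) * tr$y,
                          frame_interval = tr$frame_interval)
    for (variant in list(shifted, rotated)) {
      cl <- suppressWarnings(classify(variant, cfg))
      expect_identical(cl$mode, ref$mode)
      expect_equal(cl$D, ref$D, tolerance = 1e-9)
    }
  }
})

test_that("aggregation computes per-cell fractions, pooled mean and SEM", {
  cls <- data.frame(
    cell_id = c(rep("c1", 4), rep("c2", 2)),
    region = "all",
    mode = c("immobile", "immobile", "free", "confined", "excluded", "free"),
    D = c(0.001, 0.002, 0.3, 0.05, NA, 0.2))
  agg <- aggregate_cells(cls)
  c1 <- Filter(function(p) p$cell_id == "c1", agg$per_cell)[[1]]
  expect_equal(unname(c1$fractions), c(0.5, 0.25, 0.25))
  expect_equal(sum(c1$logD_histogram), 1)

  # two cells at the fraction extremes: pooled mean and SEM by hand
  cls2 <- data.frame(
    cell_id = c(rep("a", 3), rep("b", 3)), region = "all",
    mode = c(rep("immobile", 3), rep("free", 3)),
    D = c(0.001, 0.001, 0.001, 0.5, 0.5, 0.5))
  pooled <- aggregate_cells(cls2)$pooled$all
  expect_equal(unname(pooled$mean_fractions), c(0.5, 0, 0.5))
  expect_equal(unname(pooled$sem_fractions), c(0.5, 0, 0.5))
})

test_that("resolution estimation reproduces FWHM = 2.3 s_xy", {
  mk_cloud <- function(seed, sx, sy = sx, n = 200) {
    set.seed(seed)
    trajectory(paste0("cl", seed), 0:(n - 1),
               stats::rnorm(n, 5, sx), stats::rnorm(n, 5, sy))
  }
  frozen <- lapply(1:30, mk_cloud, sx = 0.025)
  res <- estimate_resolution(frozen)
  expect_equal(res$fwhm, 2.3 * res$s_xy)
  expect_equal(res$fwhm * 1000, 57.5, tolerance = 2 / 57.5)

  still <- lapply(1:3, function(s)
    trajectory(paste0("s", s), 0:59, rep(1, 60), rep(2, 60)))
  expect_equal(estimate_resolution(still)$fwhm, 0)

  # anisotropic convention: s_xy is the mean of the axis sigmas
  aniso <- mk_cloud(99, sx = 0.02, sy = 0.04, n = 5000)
  res_a <- estimate_resolution(list(aniso))
  expect_equal(res_a$s_xy, 0.03, tolerance = 0.05)

  expect_warning(res_b <- estimate_resolution(list(frozen[[1]],
    trajectory("tiny", 0:9, rnorm(10), rnorm(10)))), "rejected")
  expect_identical(res_b$n_clouds, 1L)
  expect_error(suppressWarnings(
    estimate_resolution(list(trajectory("tiny", 0:9, rnorm(10), rnorm(10))))))
})
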