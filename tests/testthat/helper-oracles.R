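# Independent oracles and shared fixture builders. These deliberately avoid
# the package's own code paths: the MSD oracle is a literal double loop over
# the defining sum, kept separate from compute_msd().

# brute-force MSD: for each lag n, average (x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2
# over all frame pairs separated by exactly n frames
brute_msd <- function(frames, x, y) {
  max_n <- max(frames) - min(frames)
  vals <- counts <- numeric(max_n)
  for (n in seq_len(max_n)) {
    acc <- 0
    cnt <- 0L
    for (i in seq_along(frames)) {
      j <- which(frames == frames[i] + n)
      if (length(j) == 1L) {
        acc <- acc + (x[j] - x[i])^2 + (y[j] - y[i])^2
        cnt <- cnt + 1L
      }
    }
    counts[n] <- cnt
    vals[n] <- if (cnt > 0) acc / cnt else NA_real_
  }
  list(values = vals, counts = counts)
}

random_gapped_track <- function(seed, max_len = 20L) {
  set.seed(seed)
  len <- sample(5:max_len, 1)
  frames <- sort(sample(0:(2L * max_len), len))
  trajectory(paste0("r", seed), frames,
             x = stats::rnorm(len), y = stats::rnorm(len))
}

# tiny 3-FA mask on a coarse grid for fast region tests
tiny_mask <- function() {
  fa <- matrix(0L, 10, 10)
  cell <- matrix(FALSE, 10, 10)
  cell[2:9, 2:9] <- TRUE
  fa[3:4, 3:5] <- 1L
  fa[7:8, 6:8] <- 2L
  region_mask_set(fa, cell, pixel_size = 1)
}

# structured localization scene (tight clusters), the realistic input for
# cross-correlation drift estimation
cluster_scene <- function(n_frames, drift_per_frame = c(0, 0), seed = 1,
                          n_clusters = 15, locs_per_frame = 1) {
  set.seed(seed)
  cx <- runif(n_clusters, 1, 9)
  cy <- runif(n_clusters, 1, 9)
  n <- n_frames * locs_per_frame
  fr <- rep(0:(n_frames - 1L), each = locs_per_frame)
  k <- sample(n_clusters, n, replace = TRUE)
  localization_table(data.frame(
    track_id = sprintf("c%07d", seq_len(n)), frame = fr,
    x_um = cx[k] + rnorm(n, sd = 0.03) + fr * drift_per_frame[1],
    y_um = cy[k] + rnorm(n, sd = 0.03) + fr * drift_per_frame[2],
    z_nm = runif(n, 20, 80)))
}
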