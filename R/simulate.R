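#' Simulation configuration
#'
#' Bundles the acquisition and motion parameters used by the synthetic-data
#' generator. Defaults reproduce the stated acquisition conditions: streaming
#' at 50 Hz (\eqn{\Delta t} = 20 ms) with ~25 nm per-axis pointing accuracy.
#'
#' @param frame_interval acquisition interval in seconds (default 0.02).
#' @param n_frames frames per trajectory before blinking (default 50).
#' @param pointing_accuracy localization noise sigma per axis, micrometres
#'   (default 0.0255, i.e. FWHM = 2.3 sigma = 59 nm).
#' @param D_free free-diffusion coefficient, um^2/s.
#' @param disc_radius reflecting-disc radius for confined motion, um.
#' @param D_conf diffusion coefficient inside the disc, um^2/s.
#' @param mode_proportions fractions (immobile, confined, free); must sum to 1.
#' @param blink_off_prob per-frame probability of entering a dark state.
#' @param max_gap maximum dark gap (frames) bridged inside one trajectory.
#' @param rng_seed integer seed; identical seed + config gives bit-identical
#'   output.
#' @param field_size (width, height) of the field of view in micrometres.
#' @return a list of class `sptfa_sim_config`.
#' @export
sim_config <- function(frame_interval = 0.02, n_frames = 50L,
                       pointing_accuracy = 0.0255,
                       D_free = 0.2, disc_radius = 0.1, D_conf = 0.1,
                       mode_proportions = c(immobile = 1/3, confined = 1/3,
                                            free = 1/3),
                       blink_off_prob = 0.05, max_gap = 2L,
                       rng_seed = 1L, field_size = c(20, 20)) {
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (pointing_accuracy < 0) stop("pointing_accuracy must be >= 0")
  if (D_free < 0 || D_conf < 0) stop("diffusion coefficients must be >= 0")
  if (disc_radius <= 0) stop("disc_radius must be > 0")
  if (length(mode_proportions) != 3L || any(mode_proportions < 0))
    stop("mode_proportions must be 3 nonnegative fractions")
  if (abs(sum(mode_proportions) - 1) > 1e-12)
    stop("mode_proportions must sum to 1")
  if (blink_off_prob < 0 || blink_off_prob >= 1)
    stop("blink_off_prob must be in [0, 1)")
  if (n_frames < 2) stop("n_frames must be >= 2")
  names(mode_proportions) <- c("immobile", "confined", "free")
  structure(list(frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 pointing_accuracy = pointing_accuracy,
                 D_free = D_free, disc_radius = disc_radius, D_conf = D_conf,
                 mode_proportions = mode_proportions,
                 blink_off_prob = blink_off_prob, max_gap = as.integer(max_gap),
                 rng_seed = as.integer(rng_seed),
                 field_size = as.numeric(field_size)),
            class = "sptfa_sim_config")
}

# deterministic per-trajectory substream seed derived from (seed, id)
substream_seed <- function(seed, id) {
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(id)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

reflect_in_disc <- function(p, center, R) {
  # radial reflection at the disc boundary; iterate for rare large steps
  for (k in 1:50) {
    d <- p - center
    r <- sqrt(sum(d^2))
    if (r <= R) return(p)
    p <- center + d * (2 * R - r) / r
    if (2 * R - r < 0) {      # step longer than the diameter: clamp
      p <- center + d * (R / r)
      return(p)
    }
  }
  p
}

blink_frames <- function(n_frames, off_prob, max_gap) {
  # on/off sequence; dark gaps are capped at max_gap (longer gaps would not
  # be reconnected by the tracker, so the generator never produces them).
  # First and last frame are kept on so the trajectory spans n_frames.
  on <- rep(TRUE, n_frames)
  if (off_prob > 0 && n_frames > 2L) {
    f <- 2L
    while (f < n_frames) {
      if (stats::runif(1) < off_prob) {
        gap <- min(1L + stats::rgeom(1, prob = 0.5), max_gap)
        gap <- min(gap, n_frames - f)  # keep the last frame on
        if (gap > 0) on[f:(f + gap - 1L)] <- FALSE
        f <- f + gap
      }
      f <- f + 1L
    }
  }
  which(on) - 1L
}

#' Simulate one trajectory
#'
#' Generates a single molecule's trajectory in one of three motion regimes:
#' `"free"` Brownian motion (per-axis Gaussian increments with variance
#' \eqn{2 D \Delta t}), `"confined"` Brownian motion reflected at a disc of
#' radius `disc_radius` centred on `origin`, or `"immobile"` (fixed true
#' position). Independent Gaussian localization noise of sd
#' `pointing_accuracy` is added per axis per frame; blinking removes
#' interior frames in gaps of at most `max_gap`.
#'
#' @param mode one of `"immobile"`, `"confined"`, `"free"`.
#' @param config an [sim_config()].
#' @param origin starting (and, for confined/immobile, anchor) position, um.
#' @param seed integer seed for this trajectory (`NULL` = use current RNG
#'   state).
#' @param id trajectory identifier.
#' @return an `sptfa_trajectory`.
#' @export
simulate_trajectory <- function(mode = c("free", "confined", "immobile"),
                                config = sim_config(), origin = c(0, 0),
                                seed = NULL, id = "sim") {
  mode <- match.arg(mode)
  n <- config$n_frames
  if (n <= 0) stop("n_frames must be positive")
  with_seed(seed, {
    if (mode == "immobile") {
      true_x <- rep(origin[1], n)
      true_y <- rep(origin[2], n)
    } else {
      D <- if (mode == "free") config$D_free else config$D_conf
      sd_step <- sqrt(2 * D * config$frame_interval)
      dx <- stats::rnorm(n - 1L, sd = sd_step)
      dy <- stats::rnorm(n - 1L, sd = sd_step)
      if (mode == "free") {
        true_x <- origin[1] + c(0, cumsum(dx))
        true_y <- origin[2] + c(0, cumsum(dy))
      } else {
        pos <- matrix(NA_real_, n, 2)
        pos[1, ] <- origin
        for (i in 2:n)
          pos[i, ] <- reflect_in_disc(pos[i - 1, ] + c(dx[i - 1], dy[i - 1]),
                                      origin, config$disc_radius)
        true_x <- pos[, 1]
        true_y <- pos[, 2]
      }
    }
    keep <- blink_frames(n, config$blink_off_prob, config$max_gap) + 1L
    sigma <- config$pointing_accuracy
    obs_x <- true_x[keep] + stats::rnorm(length(keep), sd = sigma)
    obs_y <- true_y[keep] + stats::rnorm(length(keep), sd = sigma)
    trajectory(id, keep - 1L, obs_x, obs_y,
               frame_interval = config$frame_interval)
  })
}

#' Simulate a labelled localization dataset
#'
#' Draws `n_tracks` trajectories with motion modes sampled from
#' `config$mode_proportions`, origins uniform inside the cell mask, and
#' returns the pooled localization table together with one ground-truth
#' label per trajectory (mode, true parameters, FA membership of the
#' origin).
#'
#' @param config an [sim_config()].
#' @param mask an `sptfa_mask_set` covering the field.
#' @param n_tracks number of trajectories (default 300).
#' @return list with elements `table` (an `sptfa_loc_table`) and `labels`
#'   (data.frame: trajectory_id, true_mode, true_D, true_disc_radius,
#'   inside_fa).
#' @export
simulate_dataset <- function(config = sim_config(), mask, n_tracks = 300L) {
  if (!inherits(mask, "sptfa_mask_set")) stop("mask must be an sptfa_mask_set")
  cell_px <- which(mask$cell_mask, arr.ind = TRUE)
  if (nrow(cell_px) == 0L) stop("empty cell mask")
  modes <- c("immobile", "confined", "free")
  set.seed(config$rng_seed)
  mode_draw <- sample(modes, n_tracks, replace = TRUE,
                      prob = config$mode_proportions)
  pick <- sample(nrow(cell_px), n_tracks, replace = TRUE)
  ps <- mask$pixel_size
  ox <- mask$origin[1]; oy <- mask$origin[2]
  # uniform position within the chosen pixel
  x0 <- ox + (cell_px[pick, "col"] - 1 + stats::runif(n_tracks)) * ps
  y0 <- oy + (cell_px[pick, "row"] - 1 + stats::runif(n_tracks)) * ps
  in_fa <- mask_value_at(mask$fa_labels,
                         floor((x0 - ox) / ps) + 1L,
                         floor((y0 - oy) / ps) + 1L) > 0L
  rows <- vector("list", n_tracks)
  labels <- data.frame(trajectory_id = sprintf("t%04d", seq_len(n_tracks)),
                       true_mode = mode_draw,
                       true_D = ifelse(mode_draw == "free", config$D_free,
                                ifelse(mode_draw == "confined", config$D_conf, 0)),
                       true_disc_radius = ifelse(mode_draw == "confined",
                                                 config$disc_radius, NA_real_),
                       inside_fa = in_fa,
                       stringsAsFactors = FALSE)
  for (i in seq_len(n_tracks)) {
    tr <- simulate_trajectory(mode_draw[i], config, origin = c(x0[i], y0[i]),
                              seed = substream_seed(config$rng_seed,
                                                    labels$trajectory_id[i]),
                              id = labels$trajectory_id[i])
    rows[[i]] <- data.frame(track_id = tr$id, frame = tr$frames,
                            x_um = tr$x, y_um = tr$y,
                            stringsAsFactors = FALSE)
  }
  tab <- localization_table(do.call(rbind, rows),
                            frame_interval = config$frame_interval,
                            pixel_size = mask$pixel_size)
  list(table = tab, labels = labels)
}

#' Synthetic focal-adhesion mask set
#'
#' Builds an elliptical cell outline containing `n_fa` elongated elliptical
#' FA regions, mimicking the geometry of manually drawn FA ROIs.
#'
#' @param field_size (width, height) in micrometres.
#' @param pixel_size raster pixel in micrometres (default 0.1, camera grid).
#' @param n_fa number of FA regions.
#' @param seed integer seed for FA placement.
#' @return an `sptfa_mask_set`.
#' @export
simulate_mask_set <- function(field_size = c(20, 20), pixel_size = 0.1,
                              n_fa = 4L, seed = 1L) {
  nx <- ceiling(field_size[1] / pixel_size)
  ny <- ceiling(field_size[2] / pixel_size)
  cx <- (seq_len(nx) - 0.5) * pixel_size
  cy <- (seq_len(ny) - 0.5) * pixel_size
  X <- matrix(cx, ny, nx, byrow = TRUE)
  Y <- matrix(cy, ny, nx)
  a <- field_size[1] / 2 * 0.9
  b <- field_size[2] / 2 * 0.9
  cell <- ((X - field_size[1] / 2) / a)^2 + ((Y - field_size[2] / 2) / b)^2 <= 1
  fa <- matrix(0L, ny, nx)
  set.seed(seed)
  k <- 0L
  while (k < n_fa) {
    # elongated ellipse (FA-like: ~2 x 0.6 um), placed in the cell periphery
    theta <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0.45, 0.75)
    fx <- field_size[1] / 2 + rad * a * cos(theta)
    fy <- field_size[2] / 2 + rad * b * sin(theta)
    la <- stats::runif(1, 0.8, 1.2)   # semi-major, um
    lb <- stats::runif(1, 0.25, 0.35) # semi-minor, um
    u <- (X - fx) * cos(theta) + (Y - fy) * sin(theta)
    v <- -(X - fx) * sin(theta) + (Y - fy) * cos(theta)
    blob <- (u / la)^2 + (v / lb)^2 <= 1
    blob <- blob & cell
    if (!any(blob) || any(fa[blob] > 0L)) next
    k <- k + 1L
    fa[blob] <- k
  }
  region_mask_set(fa, cell, pixel_size)
}

#' Simulate a paired TIRF/epifluorescence intensity fixture
#'
#' Builds an image pair on which the membrane-fraction assay (ratio of the
#' TIRF cell/background intensity ratio to the epifluorescence
#' cell/background ratio) recovers `membrane_fraction_true` exactly in the
#' noiseless case: inside the cell the epi image is `bg_level * gain` and
#' the TIRF image `bg_level * gain * membrane_fraction_true`; outside both
#' equal `bg_level`. Ground truth is therefore stated on the assay's own
#' ratio-of-ratios scale.
#'
#' @param membrane_fraction_true true membrane fraction in [0, 1].
#' @param bg_level background intensity (counts).
#' @param gain epifluorescence cell-to-background intensity ratio.
#' @param mask an `sptfa_mask_set` (cell outline used; FA labels ignored).
#' @param seed integer seed (used when `noise = "poisson"`).
#' @param noise `"none"` for the exact fixture, `"poisson"` for shot noise.
#' @return list with `tirf`, `epi` (matrices) and `bg_rois` (list of 3
#'   disjoint logical matrices outside the cell).
#' @export
simulate_intensity_pair <- function(membrane_fraction_true, bg_level = 100,
                                    gain = 4, mask = simulate_mask_set(),
                                    seed = 1L, noise = c("none", "poisson")) {
  noise <- match.arg(noise)
  f <- membrane_fraction_true
  if (f < 0 || f > 1) stop("membrane_fraction_true must be in [0, 1]")
  if (bg_level <= 0) stop("bg_level must be > 0")
  cell <- mask$cell_mask
  epi <- matrix(bg_level, nrow(cell), ncol(cell))
  tirf <- epi
  epi[cell] <- bg_level * gain
  tirf[cell] <- bg_level * gain * f
  if (noise == "poisson") {
    set.seed(seed)
    epi[] <- stats::rpois(length(epi), lambda = epi)
    tirf[] <- stats::rpois(length(tirf), lambda = tirf)
  }
  # three disjoint square background ROIs in cell-free corners
  side <- max(3L, round(min(dim(cell)) * 0.08))
  corners <- list(c(1L, 1L), c(1L, ncol(cell) - side + 1L),
                  c(nrow(cell) - side + 1L, 1L))
  bg_rois <- lapply(corners, function(cc) {
    roi <- matrix(FALSE, nrow(cell), ncol(cell))
    roi[cc[1]:(cc[1] + side - 1L), cc[2]:(cc[2] + side - 1L)] <- TRUE
    roi & !cell
  })
  list(tirf = tirf, epi = epi, bg_rois = bg_rois)
}

#' Simulate a 3D axial localization cloud
#'
#' Axial positions are Gaussian(`z_center`, `z_sigma`) truncated at
#' \eqn{z \ge 0}; lateral positions are uniform over the cell mask.
#'
#' @param z_center mean axial position, nm.
#' @param z_sigma axial spread, nm.
#' @param n number of localizations (> 0).
#' @param region an `sptfa_mask_set`; xy drawn uniformly over its cell mask.
#' @param seed integer seed.
#' @param frames optional frame indices (default `0:(n-1)`); localizations
#'   get distinct track ids.
#' @return an `sptfa_loc_table` with a `z_nm` column.
#' @export
simulate_axial_cloud <- function(z_center, z_sigma, n, region = simulate_mask_set(),
                                 seed = 1L, frames = NULL) {
  if (n <= 0) stop("n must be > 0")
  set.seed(seed)
  z <- stats::rnorm(n, z_center, z_sigma)
  while (any(z < 0)) z[z < 0] <- stats::rnorm(sum(z < 0), z_center, z_sigma)
  cell_px <- which(region$cell_mask, arr.ind = TRUE)
  pick <- sample(nrow(cell_px), n, replace = TRUE)
  ps <- region$pixel_size
  x <- region$origin[1] + (cell_px[pick, "col"] - 1 + stats::runif(n)) * ps
  y <- region$origin[2] + (cell_px[pick, "row"] - 1 + stats::runif(n)) * ps
  localization_table(
    data.frame(track_id = sprintf("z%06d", seq_len(n)),
               frame = if (is.null(frames)) 0:(n - 1L) else as.integer(frames),
               x_um = x, y_um = y, z_nm = z, stringsAsFactors = FALSE),
    frame_interval = 0.05, pixel_size = ps)
}

#' Simulate a kymograph scene of blinking emitters
#'
#' Each emitter appears from `t_on` to `t_off` seconds at position
#' `(x0, y0)` drifting at velocity `(vx, vy)` um/s; every frame while on
#' (minus blinking) yields one localization with pointing-accuracy noise.
#'
#' @param emitters data.frame with columns x0, y0 (um), vx, vy (um/s),
#'   t_on, t_off (s).
#' @param config an [sim_config()]; `n_frames` is the total movie length.
#' @param seed integer seed.
#' @return an `sptfa_loc_table`.
#' @export
simulate_kymo_scene <- function(emitters, config = sim_config(n_frames = 1500L),
                                seed = 1L) {
  set.seed(seed)
  dt <- config$frame_interval
  rows <- lapply(seq_len(nrow(emitters)), function(i) {
    e <- emitters[i, ]
    fr <- seq(floor(e$t_on / dt), min(ceiling(e$t_off / dt), config$n_frames - 1L))
    if (config$blink_off_prob > 0)
      fr <- fr[stats::runif(length(fr)) >= config$blink_off_prob]
    if (length(fr) < 2L) return(NULL)
    tt <- fr * dt
    data.frame(track_id = sprintf("e%03d", i), frame = fr,
               x_um = e$x0 + e$vx * (tt - e$t_on) +
                 stats::rnorm(length(fr), sd = config$pointing_accuracy),
               y_um = e$y0 + e$vy * (tt - e$t_on) +
                 stats::rnorm(length(fr), sd = config$pointing_accuracy),
               stringsAsFactors = FALSE)
  })
  localization_table(do.call(rbind, rows), frame_interval = dt)
}

#' Write ground-truth labels as JSON
#' @param labels the `labels` data.frame from [simulate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(labels, path) {
  jsonlite::write_json(labels, path, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(path)
}
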