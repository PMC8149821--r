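#' Classifier configuration
#'
#' Parameters of the MSD-based motion classifier. Defaults reproduce the
#' standard sptPALM analysis at 50 Hz: trajectories of at least 13 points
#' (260 ms) are analysed; the diffusion coefficient D is the initial MSD
#' slope over lags n = 1..4 divided by 4; the immobile threshold is
#' FWHM^2 / (4 * slope_points * frame_interval) = (0.059 um)^2 /
#' (4 * 4 * 0.02 s) ~ 0.011 um^2/s; the confined-diffusion model is fitted
#' over 80% of the available lags (minimum 10 points = 200 ms) and the
#' confined/free split is at tau = half that minimum fit duration (100 ms).
#'
#' @param min_points minimum localizations per analysed trajectory (13).
#' @param slope_points number of initial MSD lags in the D regression (4).
#' @param resolution_fwhm spatial resolution FWHM in micrometres (0.059).
#' @param frame_interval acquisition interval in seconds (0.02).
#' @param fit_fraction fraction of lags used by the confinement fit (0.8).
#' @param fit_min_points minimum lags in the confinement fit (10).
#' @param tau_threshold confined/free split in seconds; `NULL` (default)
#'   derives it from the config as `fit_min_points * frame_interval / 2`.
#' @param tau_max upper bound for the fitted time constant, seconds (100).
#' @return a list of class `sptfa_classifier_config`.
#' @export
classifier_config <- function(min_points = 13L, slope_points = 4L,
                              resolution_fwhm = 0.059, frame_interval = 0.02,
                              fit_fraction = 0.8, fit_min_points = 10L,
                              tau_threshold = NULL, tau_max = 100) {
  if (fit_min_points < slope_points)
    stop("fit_min_points must be >= slope_points")
  if (any(c(min_points, slope_points, resolution_fwhm, frame_interval,
            fit_fraction, fit_min_points, tau_max) <= 0) &&
      resolution_fwhm != 0)
    stop("all classifier parameters must be positive")
  if (is.null(tau_threshold))
    tau_threshold <- fit_min_points * frame_interval / 2
  structure(list(min_points = as.integer(min_points),
                 slope_points = as.integer(slope_points),
                 resolution_fwhm = resolution_fwhm,
                 frame_interval = frame_interval,
                 fit_fraction = fit_fraction,
                 fit_min_points = as.integer(fit_min_points),
                 tau_threshold = tau_threshold, tau_max = tau_max),
            class = "sptfa_classifier_config")
}

#' Construct an MSD curve
#' @param lag_frames integer lags in frames (n).
#' @param values MSD values in um^2.
#' @param pair_counts displacement pairs per lag.
#' @param frame_interval seconds.
#' @return object of class `sptfa_msd`.
#' @export
msd_curve <- function(lag_frames, values, pair_counts, frame_interval) {
  if (any(values < -1e-15)) stop("MSD values must be nonnegative")
  structure(list(lag_frames = as.integer(lag_frames),
                 lags = lag_frames * frame_interval,
                 values = as.numeric(values),
                 pair_counts = as.integer(pair_counts),
                 frame_interval = frame_interval),
            class = "sptfa_msd")
}

#' Mean squared displacement of a trajectory
#'
#' MSD(t = n * dt) = mean over i of (x_{i+n} - x_i)^2 + (y_{i+n} - y_i)^2,
#' where pairs are matched by frame-index difference (gap-aware: a blink gap
#' removes pairs rather than shifting lags). Lags with no pairs are omitted.
#'
#' @param traj an `sptfa_trajectory`.
#' @return an `sptfa_msd`.
#' @export
compute_msd <- function(traj) {
  f <- traj$frames
  x <- traj$x
  y <- traj$y
  max_n <- max(f) - min(f)
  vals <- counts <- numeric(max_n)
  for (n in seq_len(max_n)) {
    j <- match(f + n, f)
    ok <- which(!is.na(j))
    counts[n] <- length(ok)
    if (length(ok)) {
      jj <- j[ok]
      vals[n] <- mean((x[jj] - x[ok])^2 + (y[jj] - y[ok])^2)
    }
  }
  keep <- counts > 0
  msd_curve((seq_len(max_n))[keep], vals[keep], counts[keep],
            traj$frame_interval)
}

#' Initial-slope diffusion coefficient
#'
#' Ordinary least squares with free intercept through the MSD values at lags
#' n = 1..`slope_points`; D = slope / 4 (2D convention, MSD = 4 D t). The
#' intercept absorbs the localization-noise offset; negative slopes pass
#' through unclamped.
#'
#' @param msd an `sptfa_msd`.
#' @param config a [classifier_config()].
#' @return named numeric: `D` (um^2/s) and `slope` (um^2/s).
#' @export
estimate_D <- function(msd, config = classifier_config()) {
  sel <- match(seq_len(config$slope_points), msd$lag_frames)
  if (anyNA(sel))
    stop("need MSD values at lags 1..", config$slope_points)
  t <- msd$lags[sel]
  v <- msd$values[sel]
  slope <- stats::cov(t, v) / stats::var(t)
  c(D = slope / 4, slope = slope)
}

#' Immobility threshold on D
#'
#' The D value below which a molecule explored less area than the spatial
#' resolution during the initial-slope window:
#' `resolution_fwhm^2 / (4 * slope_points * frame_interval)`.
#' With the defaults (0.059 um, 4 points, 20 ms) this is ~0.011 um^2/s.
#'
#' @param config a [classifier_config()].
#' @return threshold in um^2/s.
#' @export
immobile_threshold <- function(config = classifier_config()) {
  config$resolution_fwhm^2 /
    (4 * config$slope_points * config$frame_interval)
}

confinement_model <- function(t, r_conf, tau) {
  (4 * r_conf^2 / 3) * (1 - exp(-t / tau))
}

#' Fit the confined-diffusion MSD model
#'
#' Weighted nonlinear least squares of
#' MSD(t) = (4 r_conf^2 / 3) (1 - exp(-t / tau)) over the first
#' `max(fit_min_points, floor(fit_fraction * n_lags))` lags, weights equal
#' to the per-lag pair counts (down-sampling proxy). tau is bounded in
#' (`frame_interval`/10, `tau_max`]; D_conf = r_conf^2 / (3 tau). On
#' optimizer failure or a bound-hitting tau the fit is flagged not-ok and
#' tau is reported at `tau_max` (interpreted as free diffusion downstream).
#'
#' @param msd an `sptfa_msd`.
#' @param config a [classifier_config()].
#' @return list: `r_conf` (um), `tau` (s), `D_conf` (um^2/s), `fit_ok`.
#' @export
fit_confinement <- function(msd, config = classifier_config()) {
  n_lags <- length(msd$values)
  n_fit <- min(n_lags, max(config$fit_min_points,
                           floor(config$fit_fraction * n_lags)))
  t <- msd$lags[seq_len(n_fit)]
  v <- msd$values[seq_len(n_fit)]
  w <- as.numeric(msd$pair_counts[seq_len(n_fit)])
  tau_lo <- config$frame_interval / 10
  tau_hi <- config$tau_max
  vmax <- max(v, 1e-12)
  r0 <- sqrt(3 * vmax / 4)
  i0 <- which(v >= (1 - exp(-1)) * vmax)[1]
  tau0 <- min(max(t[i0], tau_lo * 2), tau_hi / 2)
  fail <- list(r_conf = r0, tau = tau_hi,
               D_conf = r0^2 / (3 * tau_hi), fit_ok = FALSE)
  fit <- tryCatch(
    stats::nls(v ~ (4 * r^2 / 3) * (1 - exp(-t / tau)),
               start = list(r = r0, tau = tau0), weights = w,
               algorithm = "port",
               lower = c(r = 1e-6, tau = tau_lo),
               upper = c(r = 1e3, tau = tau_hi),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to direct weighted least squares on log-parameters
    obj <- function(p) {
      m <- confinement_model(t, exp(p[1]), exp(p[2]))
      sum(w * (v - m)^2)
    }
    op <- tryCatch(
      stats::optim(c(log(r0), log(tau0)), obj, method = "L-BFGS-B",
                   lower = c(log(1e-6), log(tau_lo)),
                   upper = c(log(1e3), log(tau_hi))),
      error = function(e) NULL)
    if (is.null(op)) return(fail)
    r_hat <- exp(op$par[1])
    tau_hat <- exp(op$par[2])
    converged <- op$convergence == 0
  } else {
    cf <- stats::coef(fit)
    r_hat <- cf[["r"]]
    tau_hat <- cf[["tau"]]
    converged <- isTRUE(fit$convInfo$isConv)
  }
  at_bound <- tau_hat >= tau_hi * (1 - 1e-8) || tau_hat <= tau_lo * (1 + 1e-8)
  list(r_conf = unname(r_hat),
       tau = if (at_bound && tau_hat >= tau_hi * (1 - 1e-8)) tau_hi
             else unname(tau_hat),
       D_conf = unname(r_hat^2 / (3 * tau_hat)),
       fit_ok = converged && !at_bound)
}

#' Classify a trajectory's motion mode
#'
#' Decision tree: trajectories with fewer than `min_points` localizations
#' are `excluded`; otherwise `immobile` if the initial-slope D is below
#' [immobile_threshold()]; otherwise `confined` when the fitted time
#' constant tau is below `tau_threshold` (100 ms by default), else `free`.
#' Failed confinement fits are classified free (tau at its upper bound).
#'
#' @param traj an `sptfa_trajectory`.
#' @param config a [classifier_config()].
#' @return list of class `sptfa_motion`: `mode`, `D`, `slope`, `r_conf`,
#'   `tau`, `D_conf`, `fit_ok`, `n_points`.
#' @export
classify <- function(traj, config = classifier_config()) {
  out <- list(mode = "excluded", D = NA_real_, slope = NA_real_,
              r_conf = NA_real_, tau = NA_real_, D_conf = NA_real_,
              fit_ok = NA, n_points = n_points(traj))
  class(out) <- "sptfa_motion"
  if (n_points(traj) < config$min_points) return(out)
  msd <- compute_msd(traj)
  dd <- tryCatch(estimate_D(msd, config), error = function(e) NULL)
  if (is.null(dd)) return(out)   # gapped track missing early lags
  out$D <- unname(dd["D"])
  out$slope <- unname(dd["slope"])
  if (out$D < immobile_threshold(config)) {
    out$mode <- "immobile"
    out$fit_ok <- TRUE
    return(out)
  }
  cf <- fit_confinement(msd, config)
  out$r_conf <- cf$r_conf
  out$tau <- cf$tau
  out$D_conf <- cf$D_conf
  out$fit_ok <- cf$fit_ok
  out$mode <- if (cf$tau < config$tau_threshold) "confined" else "free"
  out
}

#' @export
print.sptfa_motion <- function(x, ...) {
  cat(sprintf("<motion: %s, D = %.4g um^2/s, tau = %.3g s, r_conf = %.3g um>\n",
              x$mode, x$D, x$tau, x$r_conf))
  invisible(x)
}

#' Classify many trajectories into a tidy table
#'
#' @param trajectories list of `sptfa_trajectory`.
#' @param config a [classifier_config()].
#' @param masks optional `sptfa_mask_set` for inside/outside-FA sorting.
#' @param cell_id cell identifier attached to every row.
#' @return data.frame: id, cell_id, region, mode, D, slope, r_conf, tau,
#'   D_conf, fit_ok, n_points.
#' @export
classify_all <- function(trajectories, config = classifier_config(),
                         masks = NULL, cell_id = "cell1") {
  rows <- lapply(trajectories, function(tr) {
    m <- classify(tr, config)
    region <- if (is.null(masks)) NA_character_ else
      suppressWarnings(sort_by_region(tr, masks))
    data.frame(id = tr$id, cell_id = cell_id, region = region,
               mode = m$mode, D = m$D, slope = m$slope, r_conf = m$r_conf,
               tau = m$tau, D_conf = m$D_conf, fit_ok = m$fit_ok,
               n_points = m$n_points, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Default log10(D) histogram bin edges
#' @param n_bins number of bins (30).
#' @param range log10(D) range (c(-5, 1)).
#' @return numeric vector of edges.
#' @export
logD_breaks <- function(n_bins = 30L, range = c(-5, 1)) {
  seq(range[1], range[2], length.out = n_bins + 1L)
}

#' Aggregate classifications per cell and pool across cells
#'
#' Per cell and region: fractions of immobile/confined/free among
#' non-excluded trajectories and the normalized log10(D) histogram (sums to
#' 1; D values at or below the lowest edge — including non-positive slopes —
#' are pooled into the first bin, which also holds the sub-threshold
#' immobile population). Pooled output reports the cross-cell mean and SEM
#' of the fractions and the mean histogram, mirroring per-cell averaging.
#'
#' @param classifications data.frame from [classify_all()] (columns
#'   cell_id, region, mode, D).
#' @param breaks log10(D) histogram bin edges.
#' @return list with `per_cell` (list of cell/region summaries) and
#'   `pooled` (per region: mean fractions, SEM, mean histogram, n_cells).
#' @export
aggregate_cells <- function(classifications, breaks = logD_breaks()) {
  cl <- classifications[classifications$mode != "excluded", , drop = FALSE]
  cl$region[is.na(cl$region)] <- "all"
  groups <- split(cl, list(cl$cell_id, cl$region), drop = TRUE)
  modes <- c("immobile", "confined", "free")
  per_cell <- lapply(groups, function(g) {
    frac <- vapply(modes, function(m) mean(g$mode == m), numeric(1))
    ld <- log10(pmax(g$D, 10^breaks[1]))
    ld <- pmin(pmax(ld, breaks[1]), breaks[length(breaks)])
    h <- graphics::hist(ld, breaks = breaks, plot = FALSE)$counts
    list(cell_id = g$cell_id[1], region = g$region[1],
         fractions = frac, logD_histogram = h / sum(h),
         n_trajectories = nrow(g))
  })
  if (!length(per_cell)) {
    warning("no classified trajectories to aggregate")
    return(list(per_cell = list(), pooled = list()))
  }
  regions <- unique(vapply(per_cell, `[[`, character(1), "region"))
  pooled <- lapply(regions, function(r) {
    cells <- Filter(function(p) p$region == r, per_cell)
    fr <- do.call(rbind, lapply(cells, `[[`, "fractions"))
    hs <- do.call(rbind, lapply(cells, `[[`, "logD_histogram"))
    n <- nrow(fr)
    list(region = r, n_cells = n,
         mean_fractions = colMeans(fr),
         sem_fractions = if (n > 1) apply(fr, 2, stats::sd) / sqrt(n)
                         else rep(0, ncol(fr)) * NA,
         mean_histogram = colMeans(hs))
  })
  names(pooled) <- regions
  list(per_cell = per_cell, pooled = pooled)
}

#' Estimate the localization resolution from immobile-molecule clouds
#'
#' Each position cloud (>= 50 localizations from one long immobile
#' trajectory) is fitted with an isotropic 2D Gaussian — the maximum
#' likelihood fit, i.e. the per-axis sample standard deviations averaged
#' over x and y. The pointing accuracy s_xy is the mean fitted sigma across
#' clouds and the resolution FWHM = 2.3 * s_xy.
#'
#' @param position_clouds list of `sptfa_trajectory` (>= 50 points each).
#' @return list of class `sptfa_resolution`: `s_xy` (um), `fwhm` (um),
#'   `n_clouds`, `per_cloud_sigma`.
#' @export
estimate_resolution <- function(position_clouds) {
  ok <- vapply(position_clouds, function(tr) n_points(tr) >= 50L, logical(1))
  if (any(!ok))
    warning(sum(!ok), " cloud(s) with < 50 localizations rejected")
  position_clouds <- position_clouds[ok]
  if (!length(position_clouds)) stop("no cloud with >= 50 localizations")
  sig <- vapply(position_clouds,
                function(tr) mean(c(stats::sd(tr$x), stats::sd(tr$y))),
                numeric(1))
  s_xy <- mean(sig)
  structure(list(s_xy = s_xy, fwhm = 2.3 * s_xy,
                 n_clouds = length(position_clouds), per_cloud_sigma = sig),
            class = "sptfa_resolution")
}

#' @export
print.sptfa_resolution <- function(x, ...) {
  cat(sprintf("<resolution: s_xy = %.4g um, FWHM = %.4g um (%d clouds)>\n",
              x$s_xy, x$fwhm, x$n_clouds))
  invisible(x)
}
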