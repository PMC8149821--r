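#' Render a super-resolved PALM time-lapse
#'
#' Bins localizations into a (time, y, x) count stack in which each
#' super-frame merges `merge_frames` raw frames (default 25, i.e. 0.5 s at
#' 50 Hz). A trailing partial super-frame is dropped.
#'
#' @param table an `sptfa_loc_table`.
#' @param merge_frames raw frames per super-frame (default 25).
#' @param render_pixel rendering pixel in micrometres (default 0.03).
#' @param field (width, height) in micrometres; derived from the data when
#'   `NULL`.
#' @param origin lower-left corner of the field in micrometres.
#' @return an object of class `sptfa_timelapse`: list with `stack`
#'   (array time x ny x nx), `render_pixel`, `merge_frames`,
#'   `super_frame_duration`, `origin`.
#' @export
render_timelapse <- function(table, merge_frames = 25L, render_pixel = 0.03,
                             field = NULL, origin = c(0, 0)) {
  if (nrow(table) == 0L) stop("empty localization table")
  if (render_pixel <= 0) stop("render_pixel must be > 0")
  dt <- attr(table, "frame_interval")
  if (is.null(dt)) dt <- 0.02
  if (is.null(field))
    field <- c(max(table$x_um) - origin[1] + render_pixel,
               max(table$y_um) - origin[2] + render_pixel)
  nx <- ceiling(field[1] / render_pixel)
  ny <- ceiling(field[2] / render_pixel)
  n_super <- (max(table$frame) + 1L) %/% merge_frames
  if (n_super < 1L) stop("fewer raw frames than merge_frames")
  sf <- table$frame %/% merge_frames + 1L
  ix <- floor((table$x_um - origin[1]) / render_pixel) + 1L
  iy <- floor((table$y_um - origin[2]) / render_pixel) + 1L
  keep <- sf <= n_super & ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  stack <- array(0L, dim = c(n_super, ny, nx))
  if (any(keep)) {
    tab <- table(factor(sf[keep], levels = seq_len(n_super)),
                 factor(iy[keep], levels = seq_len(ny)),
                 factor(ix[keep], levels = seq_len(nx)))
    stack[] <- as.integer(tab)
  }
  structure(list(stack = stack, render_pixel = render_pixel,
                 merge_frames = as.integer(merge_frames),
                 super_frame_duration = merge_frames * dt,
                 origin = as.numeric(origin)),
            class = "sptfa_timelapse")
}

#' @export
print.sptfa_timelapse <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<timelapse: %d super-frames (%g s each), %d x %d px @ %g um>\n",
              d[1], x$super_frame_duration, d[2], d[3], x$render_pixel))
  invisible(x)
}

# arclength and perpendicular distance of points to a polyline
polyline_project <- function(px, py, line) {
  nseg <- nrow(line) - 1L
  best_d <- rep(Inf, length(px))
  best_s <- rep(NA_real_, length(px))
  cum <- 0
  for (k in seq_len(nseg)) {
    ax <- line[k, 1]; ay <- line[k, 2]
    bx <- line[k + 1, 1]; by <- line[k + 1, 2]
    L <- sqrt((bx - ax)^2 + (by - ay)^2)
    if (L == 0) next
    tt <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / L^2
    tt <- pmin(pmax(tt, 0), 1)
    qx <- ax + tt * (bx - ax)
    qy <- ay + tt * (by - ay)
    d <- sqrt((px - qx)^2 + (py - qy)^2)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_s[upd] <- cum + tt[upd] * L
    cum <- cum + L
  }
  list(s = best_s, d = best_d, length = cum)
}

#' Extract a kymograph along a polyline
#'
#' For every super-frame, localization counts are integrated across a band
#' of the given width centred on the sampling polyline and binned along its
#' arclength at the stack's rendering pixel. Increasing arclength defines
#' the positive (rearward) direction; orient the polyline with its start at
#' the FA distal tip.
#'
#' @param timelapse an `sptfa_timelapse`.
#' @param line 2-column matrix of polyline vertices (x, y) in micrometres.
#' @param width band width in micrometres.
#' @return matrix (time x arclength bins) of class `sptfa_kymograph`, with
#'   attributes `render_pixel` and `super_frame_duration`.
#' @export
extract_kymograph <- function(timelapse, line, width = 0.3) {
  line <- as.matrix(line)
  if (nrow(line) < 2L) stop("polyline needs at least 2 vertices")
  d <- dim(timelapse$stack)
  rp <- timelapse$render_pixel
  cx <- timelapse$origin[1] + (seq_len(d[3]) - 0.5) * rp
  cy <- timelapse$origin[2] + (seq_len(d[2]) - 0.5) * rp
  PX <- rep(cx, each = d[2])
  PY <- rep(cy, times = d[3])
  pr <- polyline_project(PX, PY, line)
  if (pr$length <= 0) stop("degenerate (zero-length) polyline")
  nbins <- ceiling(pr$length / rp)
  in_band <- pr$d <= width / 2 & !is.na(pr$s)
  sbin <- pmin(floor(pr$s / rp) + 1L, nbins)
  kymo <- matrix(0L, d[1], nbins)
  idx <- which(in_band)
  if (length(idx)) {
    flat <- matrix(timelapse$stack, d[1], d[2] * d[3])
    for (b in split(idx, sbin[idx]))
      kymo[, sbin[b[1]]] <- as.integer(rowSums(flat[, b, drop = FALSE]))
  }
  structure(kymo, class = c("sptfa_kymograph", "matrix"),
            render_pixel = rp,
            super_frame_duration = timelapse$super_frame_duration)
}

#' Detect streaks in a kymograph
#'
#' Automated surrogate for manual high-density-zone measurement: bins with
#' at least `min_count` localizations are linked into connected components
#' tolerating temporal gaps up to `max_link_gap` super-frames (blinking) and
#' spatial jumps up to `link_dist` arclength bins. Per component, the
#' per-super-frame count-weighted centroid positions are fitted with an OLS
#' line in time, whose slope is the signed speed (positive = increasing
#' arclength = rearward).
#'
#' @param kymo an `sptfa_kymograph`.
#' @param min_count detection threshold per bin (default 1).
#' @param max_link_gap temporal gap tolerance in super-frames (default 2).
#' @param link_dist spatial link tolerance in arclength bins (default 2).
#' @param min_duration minimum streak duration in super-frames (default 2).
#' @return data.frame: t_start, t_end, duration (s), speed_nm_s, n_bins.
#' @export
detect_streaks <- function(kymo, min_count = 1L, max_link_gap = 2L,
                           link_dist = 2L, min_duration = 2L) {
  if (!length(kymo)) stop("empty kymograph")
  sfd <- attr(kymo, "super_frame_duration")
  rp <- attr(kymo, "render_pixel")
  occ <- which(unclass(kymo) >= min_count, arr.ind = TRUE)
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), speed_nm_s = numeric(0),
                      n_bins = integer(0))
  if (nrow(occ) == 0L) return(empty)
  m <- nrow(occ)
  comp <- integer(m)
  cur <- 0L
  for (i in seq_len(m)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      a <- queue[[1]]
      queue <- queue[-1]
      nb <- which(comp == 0L &
                    abs(occ[, 1] - occ[a, 1]) <= max_link_gap + 1L &
                    abs(occ[, 2] - occ[a, 2]) <= link_dist)
      if (length(nb)) {
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  res <- lapply(seq_len(cur), function(cc) {
    cells <- occ[comp == cc, , drop = FALSE]
    wts <- kymo[cells]
    tf <- sort(unique(cells[, 1]))
    pos <- vapply(tf, function(t0) {
      sel <- cells[, 1] == t0
      stats::weighted.mean((cells[sel, 2] - 0.5) * rp, wts[sel])
    }, numeric(1))
    tt <- (tf - 0.5) * sfd
    n_sf <- max(tf) - min(tf) + 1L
    if (n_sf < min_duration) return(NULL)
    speed <- if (length(tf) > 1) stats::cov(tt, pos) / stats::var(tt) else 0
    data.frame(t_start = (min(tf) - 1) * sfd, t_end = max(tf) * sfd,
               duration = n_sf * sfd, speed_nm_s = speed * 1000,
               n_bins = nrow(cells))
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res)) return(empty)
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Fraction of streaks moving rearward at or above a speed cut
#'
#' @param streaks data.frame from [detect_streaks()] (needs `speed_nm_s`);
#'   optionally a `cell_id` column for per-cell reporting.
#' @param speed_cut signed speed cut in nm/s (default 2).
#' @return when no `cell_id` column: a single fraction. Otherwise a list
#'   with `per_cell` fractions, their `mean` and `sd` across cells.
#' @export
rearward_fraction <- function(streaks, speed_cut = 2) {
  if (!nrow(streaks)) stop("empty streak list")
  if (!"cell_id" %in% names(streaks))
    return(mean(streaks$speed_nm_s >= speed_cut))
  per <- vapply(split(streaks, streaks$cell_id),
                function(s) mean(s$speed_nm_s >= speed_cut), numeric(1))
  list(per_cell = per, mean = mean(per),
       sd = if (length(per) > 1) stats::sd(per) else NA_real_)
}
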