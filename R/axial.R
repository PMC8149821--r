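#' Lateral drift correction by image cross-correlation
#'
#' Localizations are binned per temporal block into 2D histograms; the
#' lateral shift of every block relative to the first is located at the
#' cross-correlation peak (sub-pixel by quadratic interpolation), linearly
#' interpolated per frame, and subtracted. Axial positions are untouched
#' (absolute z is drift-free by construction of the detection scheme).
#'
#' @param table an `sptfa_loc_table` (z column optional).
#' @param block_frames frames per block (default 2000).
#' @param corr_pixel histogram pixel for the correlation in micrometres
#'   (default 0.05).
#' @return list: `table` (corrected), `drift` (data.frame block,
#'   frame_center, dx_um, dy_um).
#' @export
drift_correct_xy <- function(table, block_frames = 2000L, corr_pixel = 0.05) {
  fr <- table$frame
  block <- fr %/% block_frames
  blocks <- sort(unique(block))
  n_blocks <- max(block) + 1L
  if (n_blocks < 2L) {
    drift <- data.frame(block = 0L,
                        frame_center = (min(fr) + max(fr)) / 2,
                        dx_um = 0, dy_um = 0)
    return(list(table = table, drift = drift))
  }
  x0 <- min(table$x_um); y0 <- min(table$y_um)
  nx <- max(32L, ceiling((max(table$x_um) - x0) / corr_pixel) + 1L)
  ny <- max(32L, ceiling((max(table$y_um) - y0) / corr_pixel) + 1L)
  # histograms are zero-padded to twice the extent so the FFT correlation
  # is linear, not circular: shifts up to the full field are unambiguous
  bin2d <- function(sel) {
    ix <- pmin(floor((table$x_um[sel] - x0) / corr_pixel) + 1L, nx)
    iy <- pmin(floor((table$y_um[sel] - y0) / corr_pixel) + 1L, ny)
    h <- matrix(0, 2L * ny, 2L * nx)
    tab <- table(factor(iy, levels = seq_len(ny)),
                 factor(ix, levels = seq_len(nx)))
    h[seq_len(ny), seq_len(nx)] <- as.numeric(tab)
    h
  }
  ref <- bin2d(block == blocks[1])
  Fref <- stats::fft(ref)
  shifts <- matrix(NA_real_, n_blocks, 2)
  shifts[blocks[1] + 1L, ] <- 0
  for (b in setdiff(blocks, blocks[1])) {
    h <- bin2d(block == b)
    # cross-correlation: peak at the displacement of h relative to ref
    cc <- Re(stats::fft(Fref * Conj(stats::fft(h)), inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    sub <- function(axis_len, p, get) {
      lo <- get(ifelse(p == 1L, axis_len, p - 1L))
      hi <- get(ifelse(p == axis_len, 1L, p + 1L))
      c0 <- get(p)
      den <- lo - 2 * c0 + hi
      if (den == 0) 0 else 0.5 * (lo - hi) / den
    }
    dy_pix <- (pk[1] - 1) + sub(2L * ny, pk[1], function(i) cc[i, pk[2]])
    dx_pix <- (pk[2] - 1) + sub(2L * nx, pk[2], function(i) cc[pk[1], i])
    if (dy_pix > ny) dy_pix <- dy_pix - 2L * ny
    if (dx_pix > nx) dx_pix <- dx_pix - 2L * nx
    shifts[b + 1L, ] <- -c(dx_pix, dy_pix) * corr_pixel
  }
  # blocks without localizations: interpolate from neighbours
  centers <- (seq_len(n_blocks) - 0.5) * block_frames
  for (ax in 1:2) {
    known <- which(!is.na(shifts[, ax]))
    if (length(known) < n_blocks)
      shifts[, ax] <- stats::approx(centers[known], shifts[known, ax],
                                    xout = centers, rule = 2)$y
  }
  # per-frame shift: linear interpolation between block centres, linear
  # extrapolation beyond the first/last centre (handles steady drift)
  interp <- function(s) {
    y <- stats::approx(centers, s, xout = fr, rule = 2)$y
    nb <- length(centers)
    if (nb >= 2) {
      lo <- fr < centers[1]
      hi <- fr > centers[nb]
      slope_lo <- (s[2] - s[1]) / (centers[2] - centers[1])
      slope_hi <- (s[nb] - s[nb - 1]) / (centers[nb] - centers[nb - 1])
      y[lo] <- s[1] + (fr[lo] - centers[1]) * slope_lo
      y[hi] <- s[nb] + (fr[hi] - centers[nb]) * slope_hi
    }
    y
  }
  fx <- interp(shifts[, 1])
  fy <- interp(shifts[, 2])
  out <- table
  out$x_um <- table$x_um - fx
  out$y_um <- table$y_um - fy
  list(table = out,
       drift = data.frame(block = seq_len(n_blocks) - 1L,
                          frame_center = centers,
                          dx_um = shifts[, 1], dy_um = shifts[, 2]))
}

#' Render a mean-z super-resolution map
#'
#' Each pixel (default 15 nm) holds the mean axial position of the
#' localizations falling in it; molecules above `display_cut` (150 nm) are
#' discarded before averaging to keep the contrast in the adhesion/membrane
#' layer. The map is smoothed with a mean filter (default 5 x 5) over
#' defined pixels; pixels without localizations stay undefined (NA).
#'
#' @param table an `sptfa_loc_table` with `z_nm`.
#' @param mask an `sptfa_mask_set` (supplies field extent and origin).
#' @param render_pixel micrometres (default 0.015).
#' @param display_cut nm; localizations above it are excluded (default 150).
#' @param kernel mean-filter kernel size (odd, default 5).
#' @return matrix of class `sptfa_meanz` (NA = undefined), with attributes
#'   `render_pixel` and `origin`.
#' @export
render_mean_z <- function(table, mask, render_pixel = 0.015,
                          display_cut = 150, kernel = 5L) {
  if (!"z_nm" %in% names(table)) stop("table has no z_nm column")
  sel <- table$z_nm <= display_cut
  x <- table$x_um[sel]; y <- table$y_um[sel]; z <- table$z_nm[sel]
  ext <- dim(mask$cell_mask) * mask$pixel_size
  nx <- ceiling(ext[2] / render_pixel)
  ny <- ceiling(ext[1] / render_pixel)
  ix <- floor((x - mask$origin[1]) / render_pixel) + 1L
  iy <- floor((y - mask$origin[2]) / render_pixel) + 1L
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  idx <- (ix[ok] - 1L) * ny + iy[ok]
  sums <- counts <- numeric(ny * nx)
  agg_s <- tapply(z[ok], idx, sum)
  agg_n <- tapply(z[ok], idx, length)
  sums[as.integer(names(agg_s))] <- agg_s
  counts[as.integer(names(agg_n))] <- agg_n
  m <- matrix(ifelse(counts > 0, sums / counts, NA_real_), ny, nx)
  if (kernel > 1L) {
    half <- kernel %/% 2L
    vals <- matrix(0, ny, nx)
    nn <- matrix(0, ny, nx)
    defined <- !is.na(m)
    m0 <- ifelse(defined, m, 0)
    for (dy in -half:half) for (dx in -half:half) {
      ys <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
      xs <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
      vals <- vals + m0[ys, xs]
      nn <- nn + defined[ys, xs]
    }
    sm <- ifelse(nn > 0, vals / nn, NA_real_)
    sm[!defined] <- NA_real_
    m <- sm
  }
  structure(m, class = c("sptfa_meanz", "matrix"),
            render_pixel = render_pixel, origin = mask$origin)
}

fit_gaussian_peak <- function(centers, counts, mode_idx, half_window = 3L,
                              max_window = 10L) {
  bw <- if (length(centers) > 1) centers[2] - centers[1] else 1
  for (w in half_window:max_window) {
    lo <- max(1L, mode_idx - w)
    hi <- min(length(centers), mode_idx + w)
    cc <- centers[lo:hi]
    nn <- counts[lo:hi]
    if (sum(nn > 0) < 4L) next
    fit <- tryCatch(
      stats::nls(nn ~ A * exp(-(cc - mu)^2 / (2 * s^2)),
                 start = list(A = max(nn), mu = centers[mode_idx],
                              s = max(bw, (hi - lo) * bw / 4)),
                 algorithm = "port",
                 lower = c(A = 0, mu = min(cc), s = bw / 10),
                 upper = c(A = Inf, mu = max(cc), s = diff(range(cc)) + bw)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      # stable when the window spans at least 1.5 fitted sigma per side
      if (w < max_window && (hi - lo) * bw / 2 < 1.5 * cf[["s"]]) next
      se <- tryCatch(summary(fit)$coefficients["mu", "Std. Error"],
                     error = function(e) NA_real_)
      if (cf[["mu"]] > min(cc) && cf[["mu"]] < max(cc))
        return(list(z_peak = cf[["mu"]], z_peak_se = se, sigma = cf[["s"]]))
    }
  }
  # fall back: count-weighted mean of the initial window
  lo <- max(1L, mode_idx - half_window)
  hi <- min(length(centers), mode_idx + half_window)
  list(z_peak = stats::weighted.mean(centers[lo:hi], counts[lo:hi]),
       z_peak_se = NA_real_, sigma = NA_real_)
}

#' Axial localization profile per region
#'
#' Histograms the axial positions of all localizations inside and outside
#' the FA regions (full z range, every detection included), estimates the
#' peak position z_peak by Gaussian fitting around the dominant mode, and
#' computes box-plot statistics on the subset with z <= 200 nm.
#'
#' @param table an `sptfa_loc_table` with `z_nm`.
#' @param masks an `sptfa_mask_set`.
#' @param bin_width histogram bin in nm (default 10).
#' @param box_cut nm; localizations above it are excluded from the box
#'   statistics only (default 200).
#' @param min_locs regions with fewer localizations get a low-confidence
#'   flag (default 100).
#' @return named list (`inside_fa`, `outside_fa`) of `sptfa_axial_profile`
#'   objects: region, breaks, counts, z_peak, z_peak_se, box_stats,
#'   n_localizations, low_confidence.
#' @export
z_profile <- function(table, masks, bin_width = 10, box_cut = 200,
                      min_locs = 100L) {
  if (!"z_nm" %in% names(table)) stop("table has no z_nm column")
  px <- loc_to_pixel(table$x_um, table$y_um, masks)
  in_cell <- mask_value_at(masks$cell_mask, px$ix, px$iy, outside = FALSE)
  in_fa <- mask_value_at(masks$fa_labels, px$ix, px$iy) > 0L
  sets <- list(inside_fa = in_fa, outside_fa = in_cell & !in_fa)
  Map(function(sel, region_name) {
    z <- table$z_nm[sel]
    if (!length(z)) {
      warning("region with no localizations")
      return(NULL)
    }
    lo <- floor(min(z) / bin_width) * bin_width
    hi <- ceiling(max(z) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi, by = bin_width)
    h <- graphics::hist(z, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)
    pk <- fit_gaussian_peak(h$mids, h$counts, which.max(h$counts))
    zbox <- z[z <= box_cut]
    structure(list(
      region = region_name,
      breaks = breaks, counts = h$counts,
      z_peak = pk$z_peak, z_peak_se = pk$z_peak_se, z_sigma = pk$sigma,
      box_stats = c(median = stats::median(zbox), mean = mean(zbox),
                    q25 = unname(stats::quantile(zbox, 0.25)),
                    q75 = unname(stats::quantile(zbox, 0.75))),
      n_localizations = length(z),
      low_confidence = length(z) < min_locs),
      class = "sptfa_axial_profile")
  }, sets, names(sets))
}

#' @export
print.sptfa_axial_profile <- function(x, ...) {
  cat(sprintf("<axial profile %s: z_peak = %.1f nm (n = %d%s)>\n",
              x$region, x$z_peak, x$n_localizations,
              if (x$low_confidence) ", low confidence" else ""))
  invisible(x)
}
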