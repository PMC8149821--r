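#' Pooled background level from a set of background ROIs
#'
#' Equal-weight mean of the per-ROI mean intensities (at least 3 ROIs,
#' disjoint from the cell).
#' @param image intensity matrix.
#' @param bg_rois list of logical matrices.
#' @return pooled background (counts).
#' @keywords internal
pooled_background <- function(image, bg_rois) {
  mean(vapply(bg_rois, function(roi) mean(image[roi]), numeric(1)))
}

check_bg_rois <- function(bg_rois, cell_mask, shape) {
  if (length(bg_rois) < 3L)
    stop("need at least 3 background ROIs")
  for (roi in bg_rois) {
    if (!identical(dim(roi), shape)) stop("background ROI shape mismatch")
    if (!any(roi)) stop("empty background ROI")
    if (any(roi & cell_mask)) stop("background ROI overlaps the cell mask")
  }
}

drop_saturated <- function(image, sat_level) {
  if (is.null(sat_level)) return(image)
  n_sat <- sum(image >= sat_level)
  if (n_sat > 0) {
    warning(n_sat, " saturated pixel(s) excluded")
    image[image >= sat_level] <- NA_real_
  }
  image
}

#' Membrane fraction from paired TIRF / epifluorescence images
#'
#' Estimates the fraction of a protein residing at the plasma membrane by
#' comparing the membrane-level signal (TIRF) with the whole-cell signal
#' (epifluorescence), using the same cell and background regions on both
#' images:
#' \deqn{n_{membrane} = Fluo_{TIRF} / BG_{TIRF}, \quad
#'       n_{total} = Fluo_{epi} / BG_{epi}, \quad
#'       F_{membrane} = n_{membrane} / n_{total}}
#' where each Fluo is the mean intensity over the cell mask and each BG the
#' mean of at least three background-ROI means.
#'
#' @param tirf_image,epi_image intensity matrices of identical shape.
#' @param cell_mask logical matrix (TRUE inside the cell).
#' @param bg_rois list of >= 3 logical matrices, disjoint from the cell.
#' @param sat_level optional saturation ceiling; pixels at/above it are
#'   excluded with a warning.
#' @return list of class `sptfa_membrane_fraction`: fluo_tirf, bg_tirf,
#'   fluo_epi, bg_epi, n_membrane, n_total, f_membrane.
#' @export
membrane_fraction <- function(tirf_image, epi_image, cell_mask, bg_rois,
                              sat_level = NULL) {
  if (!identical(dim(tirf_image), dim(epi_image)))
    stop("TIRF and epi images must share shape")
  cell_mask <- as.matrix(cell_mask)
  storage.mode(cell_mask) <- "logical"
  check_bg_rois(bg_rois, cell_mask, dim(tirf_image))
  tirf_image <- drop_saturated(tirf_image, sat_level)
  epi_image <- drop_saturated(epi_image, sat_level)
  bg_tirf <- pooled_background(tirf_image, bg_rois)
  bg_epi <- pooled_background(epi_image, bg_rois)
  if (bg_tirf <= 0 || bg_epi <= 0) stop("background must be > 0")
  fluo_tirf <- mean(tirf_image[cell_mask], na.rm = TRUE)
  fluo_epi <- mean(epi_image[cell_mask], na.rm = TRUE)
  n_membrane <- fluo_tirf / bg_tirf
  n_total <- fluo_epi / bg_epi
  structure(list(fluo_tirf = fluo_tirf, bg_tirf = bg_tirf,
                 fluo_epi = fluo_epi, bg_epi = bg_epi,
                 n_membrane = n_membrane, n_total = n_total,
                 f_membrane = n_membrane / n_total),
            class = "sptfa_membrane_fraction")
}

#' @export
print.sptfa_membrane_fraction <- function(x, ...) {
  cat(sprintf("<membrane fraction: %.4g (n_membrane = %.4g, n_total = %.4g)>\n",
              x$f_membrane, x$n_membrane, x$n_total))
  invisible(x)
}

#' Focal-adhesion enrichment of a fluorescence image
#'
#' \deqn{enrichment = \frac{\langle I \rangle_{inside FA} - \langle I
#'   \rangle_{background}}{\langle I \rangle_{outside FA} - \langle I
#'   \rangle_{background}}}
#' where "outside FA" is the cell mask minus the FA mask and the background
#' is measured outside the cell. An outside-FA mean at or below background
#' makes the ratio meaningless and raises a classed error
#' (`sptfa_invalid_measurement`) carrying the measured means.
#'
#' @param image intensity matrix.
#' @param fa_mask logical matrix of FA pixels (subset of `cell_mask`).
#' @param cell_mask logical matrix.
#' @param bg_rois list of >= 3 logical background ROIs outside the cell.
#' @param sat_level optional saturation ceiling.
#' @return list of class `sptfa_enrichment`: mean_in_fa, mean_out_fa,
#'   mean_bg, enrichment.
#' @export
fa_enrichment <- function(image, fa_mask, cell_mask, bg_rois,
                          sat_level = NULL) {
  fa_mask <- as.matrix(fa_mask)
  storage.mode(fa_mask) <- "logical"
  cell_mask <- as.matrix(cell_mask)
  storage.mode(cell_mask) <- "logical"
  if (any(fa_mask & !cell_mask)) stop("fa_mask must lie inside cell_mask")
  check_bg_rois(bg_rois, cell_mask, dim(image))
  image <- drop_saturated(image, sat_level)
  mean_bg <- pooled_background(image, bg_rois)
  mean_in <- mean(image[fa_mask], na.rm = TRUE)
  mean_out <- mean(image[cell_mask & !fa_mask], na.rm = TRUE)
  if (!(mean_out > mean_bg)) {
    cond <- structure(
      class = c("sptfa_invalid_measurement", "error", "condition"),
      list(message = sprintf(
             paste0("invalid FA-enrichment measurement: outside-FA mean ",
                    "(%.4g) is not above background (%.4g)"),
             mean_out, mean_bg),
           call = sys.call(-1),
           mean_in_fa = mean_in, mean_out_fa = mean_out, mean_bg = mean_bg))
    stop(cond)
  }
  structure(list(mean_in_fa = mean_in, mean_out_fa = mean_out,
                 mean_bg = mean_bg,
                 enrichment = (mean_in - mean_bg) / (mean_out - mean_bg)),
            class = "sptfa_enrichment")
}

#' @export
print.sptfa_enrichment <- function(x, ...) {
  cat(sprintf("<FA enrichment: %.4g (in = %.4g, out = %.4g, bg = %.4g)>\n",
              x$enrichment, x$mean_in_fa, x$mean_out_fa, x$mean_bg))
  invisible(x)
}
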