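#' Construct a trajectory
#'
#' A trajectory is one molecule's time-ordered sequence of 2D (optionally 3D)
#' localizations. Coordinates are in micrometres (x, y) and nanometres (z);
#' frame indices are 0-based integers and may contain gaps (blinking);
#' the time of frame \eqn{f} is \eqn{f \cdot \Delta t}.
#'
#' @param id trajectory identifier (coerced to character).
#' @param frames integer frame indices, strictly increasing, length >= 2.
#' @param x,y numeric coordinates in micrometres, same length as `frames`.
#' @param z optional numeric axial positions in nanometres.
#' @param frame_interval acquisition interval \eqn{\Delta t} in seconds.
#' @return an object of class `sptfa_trajectory`.
#' @export
trajectory <- function(id, frames, x, y, z = NULL, frame_interval = 0.02) {
  frames <- as.integer(frames)
  if (length(frames) < 2L)
    stop("a trajectory needs at least 2 localizations")
  if (any(diff(frames) <= 0L))
    stop("frame indices must be strictly increasing")
  if (length(x) != length(frames) || length(y) != length(frames))
    stop("x, y must match frames in length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x, y must be finite")
  if (!is.null(z) && length(z) != length(frames))
    stop("z must match frames in length")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(
    list(id = as.character(id), frames = frames,
         x = as.numeric(x), y = as.numeric(y),
         z = if (is.null(z)) NULL else as.numeric(z),
         frame_interval = as.numeric(frame_interval)),
    class = "sptfa_trajectory")
}

#' @export
print.sptfa_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s: %d points, frames %d..%d, dt = %g s>\n",
              x$id, length(x$frames), min(x$frames), max(x$frames),
              x$frame_interval))
  invisible(x)
}

#' Number of localizations in a trajectory
#' @param traj an `sptfa_trajectory`.
#' @return integer point count.
#' @export
n_points <- function(traj) length(traj$frames)

mandatory_loc_cols <- c("track_id", "frame", "x_um", "y_um")

#' Construct / validate a localization table
#'
#' A localization table is a data.frame with one row per localization and
#' mandatory columns `track_id`, `frame`, `x_um`, `y_um`; optional columns
#' `z_nm` and `photons` are recognised, any further columns are preserved.
#' `(track_id, frame)` pairs must be unique.
#'
#' @param df data.frame of localizations.
#' @param frame_interval acquisition interval in seconds (metadata).
#' @param pixel_size camera pixel size in micrometres (metadata, optional).
#' @return the validated data.frame with class `sptfa_loc_table`.
#' @export
localization_table <- function(df, frame_interval = 0.02, pixel_size = NA_real_) {
  if (!is.data.frame(df)) stop("df must be a data.frame")
  missing_cols <- setdiff(mandatory_loc_cols, names(df))
  if (length(missing_cols))
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  for (col in intersect(c("frame", "x_um", "y_um", "z_nm", "photons"), names(df))) {
    if (!is.numeric(df[[col]]))
      stop("column ", col, " must be numeric")
  }
  if (nrow(df) && any(!is.finite(df$x_um) | !is.finite(df$y_um)))
    stop("non-finite coordinates in x_um/y_um")
  if (anyDuplicated(df[c("track_id", "frame")]))
    stop("duplicate (track_id, frame) pairs")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  df <- as.data.frame(df)
  attr(df, "frame_interval") <- frame_interval
  attr(df, "pixel_size") <- pixel_size
  class(df) <- c("sptfa_loc_table", "data.frame")
  df
}

#' Read a localization table from delimited text
#'
#' @param path file path.
#' @param sep field separator: `","` (default) or `"\t"`.
#' @param frame_interval acquisition interval in seconds.
#' @param pixel_size optional camera pixel size in micrometres.
#' @return an `sptfa_loc_table`.
#' @export
read_localizations <- function(path, sep = ",", frame_interval = 0.02,
                               pixel_size = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  localization_table(df, frame_interval = frame_interval,
                     pixel_size = pixel_size)
}

#' Write a localization table as comma-separated text
#'
#' @param table an `sptfa_loc_table` (or plain data.frame with the mandatory
#'   columns).
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, sep = ",") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a localization table into trajectories
#'
#' One trajectory per `track_id`, rows sorted by frame. Frame gaps are kept
#' as-is (not renumbered). Tracks with fewer than 2 localizations are dropped
#' with a warning.
#'
#' @param table an `sptfa_loc_table`.
#' @return a named list of `sptfa_trajectory` objects.
#' @export
build_trajectories <- function(table) {
  dt <- attr(table, "frame_interval")
  if (is.null(dt)) dt <- 0.02
  pieces <- split(as.data.frame(table), table$track_id)
  short <- vapply(pieces, nrow, integer(1)) < 2L
  if (any(short)) {
    warning(sum(short), " track(s) with < 2 localizations dropped")
    pieces <- pieces[!short]
  }
  lapply(pieces, function(p) {
    p <- p[order(p$frame), , drop = FALSE]
    trajectory(p$track_id[1], p$frame, p$x_um, p$y_um,
               z = if ("z_nm" %in% names(p)) p$z_nm else NULL,
               frame_interval = dt)
  })
}

#' Construct a region mask set
#'
#' Holds the rasterized focal-adhesion (FA) label image and the cell outline
#' mask on a common pixel grid. Rasters are matrices indexed `[iy, ix]` with
#' row 1 at the bottom (y increases upward); the continuous point
#' \eqn{(x, y)} in micrometres maps to pixel
#' `ix = floor((x - origin[1]) / pixel_size) + 1` (same for y).
#'
#' @param fa_labels integer matrix; 0 = outside any FA, k > 0 = FA number k.
#' @param cell_mask logical matrix, same shape; TRUE inside the cell.
#' @param pixel_size pixel edge in micrometres.
#' @param origin (x, y) of the raster's lower-left corner in micrometres.
#' @return an object of class `sptfa_mask_set`.
#' @export
region_mask_set <- function(fa_labels, cell_mask, pixel_size,
                            origin = c(0, 0)) {
  fa_labels <- as.matrix(fa_labels)
  storage.mode(fa_labels) <- "integer"
  cell_mask <- as.matrix(cell_mask)
  storage.mode(cell_mask) <- "logical"
  if (!identical(dim(fa_labels), dim(cell_mask)))
    stop("fa_labels and cell_mask must share shape")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (any(fa_labels > 0L & !cell_mask))
    stop("labeled FA pixels must lie inside the cell mask")
  structure(list(fa_labels = fa_labels, cell_mask = cell_mask,
                 pixel_size = as.numeric(pixel_size),
                 origin = as.numeric(origin)),
            class = "sptfa_mask_set")
}

#' @export
print.sptfa_mask_set <- function(x, ...) {
  cat(sprintf("<mask set: %d x %d px @ %g um, %d FA region(s)>\n",
              nrow(x$fa_labels), ncol(x$fa_labels), x$pixel_size,
              length(setdiff(unique(as.vector(x$fa_labels)), 0L))))
  invisible(x)
}

#' Map continuous coordinates to raster pixel indices
#'
#' @param x,y coordinates in micrometres.
#' @param masks an `sptfa_mask_set` (supplies pixel size and origin).
#' @return data.frame with integer columns `ix`, `iy` (1-based; may fall
#'   outside the raster).
#' @export
loc_to_pixel <- function(x, y, masks) {
  data.frame(ix = as.integer(floor((x - masks$origin[1]) / masks$pixel_size)) + 1L,
             iy = as.integer(floor((y - masks$origin[2]) / masks$pixel_size)) + 1L)
}

mask_value_at <- function(raster, ix, iy, outside = 0L) {
  ok <- ix >= 1L & ix <= ncol(raster) & iy >= 1L & iy <= nrow(raster)
  out <- rep(outside, length(ix))
  if (any(ok)) out[ok] <- raster[cbind(iy[ok], ix[ok])]
  out
}

#' Sort a trajectory into inside/outside focal-adhesion regions
#'
#' A trajectory is labelled `inside_fa` when at least `threshold` (default
#' 50%) of its localizations fall on FA-labelled pixels; ties go inside.
#' Trajectories entirely outside the cell mask are excluded (`NA` label)
#' with a warning.
#'
#' @param traj an `sptfa_trajectory`.
#' @param masks an `sptfa_mask_set`.
#' @param threshold fraction of in-FA localizations required (default 0.5).
#' @return `"inside_fa"`, `"outside_fa"`, or `NA_character_` if excluded.
#' @export
sort_by_region <- function(traj, masks, threshold = 0.5) {
  px <- loc_to_pixel(traj$x, traj$y, masks)
  in_cell <- mask_value_at(masks$cell_mask, px$ix, px$iy, outside = FALSE)
  if (!any(in_cell)) {
    warning("trajectory ", traj$id, " entirely outside the cell mask; excluded")
    return(NA_character_)
  }
  in_fa <- mask_value_at(masks$fa_labels, px$ix, px$iy, outside = 0L) > 0L
  if (mean(in_fa) >= threshold) "inside_fa" else "outside_fa"
}

#' Write a mask set to a plain-text (JSON) file
#' @param masks an `sptfa_mask_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_set <- function(masks, path) {
  jsonlite::write_json(
    list(fa_labels = masks$fa_labels, cell_mask = masks$cell_mask,
         pixel_size = masks$pixel_size, origin = masks$origin),
    path, matrix = "rowmajor", digits = NA)
  invisible(path)
}

#' Read a mask set written by [write_mask_set()]
#' @param path input path.
#' @return an `sptfa_mask_set`.
#' @export
read_mask_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  region_mask_set(j$fa_labels, j$cell_mask == 1 | j$cell_mask == TRUE,
                  j$pixel_size, j$origin)
}
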