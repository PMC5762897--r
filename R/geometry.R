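#' Migration-chip device geometry
#'
#' Describes the physical layout of a two-sided microfluidic migration chip:
#' two outer loading channels feeding opposing arrays of narrow migration
#' channels that meet a central retrieval channel. The default geometry is a
#' 900-channel device (450 channels per side), each migration channel
#' 30 um wide and 1 mm long. Channel height (5 um for migration channels,
#' 40 um for main channels) is carried as metadata only; images and analysis
#' are two-dimensional top views.
#'
#' The image frame is laid out column-wise as
#' `| left main | left channels (length L) | central | right channels | right main |`,
#' with channels stacked row-wise at `channel_pitch_um` spacing. Cells enter
#' at the loading side; migration distance increases toward the central
#' channel (+x for the left side, -x for the right side).
#'
#' @param n_channels_per_side Migration channels on each side of the central
#'   channel (default 450).
#' @param n_sides Number of channel arrays (fixed at 2 for this device).
#' @param channel_width_um Migration-channel width in micrometers.
#' @param channel_length_um Migration-channel length in micrometers (1 mm).
#' @param channel_pitch_um Center-to-center spacing of adjacent channels;
#'   must exceed `channel_width_um`.
#' @param main_channel_width_um Width of each outer loading channel rendered
#'   in the image frame.
#' @param central_channel_width_um Width of the central retrieval channel.
#' @param pixel_size_um Microscope pixel calibration (um per pixel). The
#'   default of 1 makes pixel and micrometer coordinates coincide.
#' @param channel_height_um,main_channel_height_um Channel heights, recorded
#'   as metadata (rendering is 2-D).
#' @return An object of class `device_geometry`: a list of the above fields
#'   plus `image_shape_px = c(rows, cols)` derived from the layout.
#' @examples
#' g <- device_geometry(n_channels_per_side = 10)
#' g$image_shape_px
#' @export
device_geometry <- function(n_channels_per_side = 450,
                            n_sides = 2,
                            channel_width_um = 30,
                            channel_length_um = 1000,
                            channel_pitch_um = 40,
                            main_channel_width_um = 50,
                            central_channel_width_um = 100,
                            pixel_size_um = 1,
                            channel_height_um = 5,
                            main_channel_height_um = 40) {
  stopifnot(n_channels_per_side >= 1, n_sides == 2)
  lens <- c(channel_width_um, channel_length_um, channel_pitch_um,
            main_channel_width_um, central_channel_width_um, pixel_size_um)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all geometry lengths must be strictly positive", call. = FALSE)
  if (channel_pitch_um <= channel_width_um)
    stop("channel_pitch_um must exceed channel_width_um", call. = FALSE)
  px <- pixel_size_um
  rows <- ceiling(n_channels_per_side * channel_pitch_um / px)
  cols <- ceiling((2 * main_channel_width_um + 2 * channel_length_um +
                     central_channel_width_um) / px)
  g <- list(
    n_channels_per_side = as.integer(n_channels_per_side),
    n_sides = 2L,
    channel_width_um = channel_width_um,
    channel_length_um = channel_length_um,
    channel_pitch_um = channel_pitch_um,
    main_channel_width_um = main_channel_width_um,
    central_channel_width_um = central_channel_width_um,
    pixel_size_um = pixel_size_um,
    channel_height_um = channel_height_um,
    main_channel_height_um = main_channel_height_um,
    image_shape_px = c(rows = as.integer(rows), cols = as.integer(cols))
  )
  class(g) <- "device_geometry"
  g
}

#' @export
print.device_geometry <- function(x, ...) {
  cat(sprintf(
    "Migration-chip geometry: %d channels (%d per side), %g x %g um each\n",
    x$n_channels_per_side * x$n_sides, x$n_channels_per_side,
    x$channel_width_um, x$channel_length_um))
  cat(sprintf("  pitch %g um, pixel size %g um/px, image %d x %d px\n",
              x$channel_pitch_um, x$pixel_size_um,
              x$image_shape_px[1], x$image_shape_px[2]))
  invisible(x)
}

#' Total number of migration channels on a device
#' @param geometry A [device_geometry()].
#' @return Integer channel count (900 for the default device).
#' @export
n_channels <- function(geometry) {
  geometry$n_channels_per_side * geometry$n_sides
}

# Backward margin (px) kept in each channel ROI so that a cell footprint
# straddling the entrance line is still captured whole: maximum cell radius
# (7.5 um) plus the anti-aliased rim and one guard pixel.
roi_margin_px <- function(geometry) {
  ceiling(9 / geometry$pixel_size_um)
}

#' Channel regions of interest from a geometry template
#'
#' Lays out one rectangular ROI per migration channel directly from the
#' device geometry (the chip layout is known by design, so segmentation is
#' template-based). Each ROI records the entrance pixel on the loading side
#' and the axis direction of increasing migration distance (+1 columns for
#' left-side channels, -1 for right-side). ROIs include a short backward
#' margin into the loading channel and a forward margin into the central
#' channel so that cell footprints straddling either end are captured;
#' ROIs of distinct channels are pairwise disjoint.
#'
#' @param geometry A [device_geometry()].
#' @return A data frame with one row per channel: `channel_index` (1-based
#'   within each side), `side` (`"left"`/`"right"`), `entrance_row`,
#'   `entrance_col`, `axis` (+1/-1), and the bounding box
#'   `row_min`, `row_max`, `col_min`, `col_max` (1-based, inclusive).
#' @export
channel_rois <- function(geometry) {
  g <- geometry
  px <- g$pixel_size_um
  n <- g$n_channels_per_side
  L_px <- round(g$channel_length_um / px)
  main_px <- round(g$main_channel_width_um / px)
  central_px <- round(g$central_channel_width_um / px)
  half_w <- floor(g$channel_width_um / px / 2)
  margin <- roi_margin_px(g)
  if (central_px <= 2 * margin)
    stop("central channel too narrow for ROI margins at this pixel size",
         call. = FALSE)
  rows_img <- g$image_shape_px[[1]]
  cols_img <- g$image_shape_px[[2]]

  row_center <- round((seq_len(n) - 0.5) * g$channel_pitch_um / px)
  row_min <- pmax(1L, row_center - half_w)
  row_max <- pmin(rows_img, row_center + half_w)

  # left side: entrance at end of left main channel, axis +x
  ent_left <- main_px
  # right side: entrance at start of right main channel, axis -x
  ent_right <- cols_img - main_px + 1L

  left <- data.frame(
    channel_index = seq_len(n), side = "left",
    entrance_row = row_center, entrance_col = ent_left, axis = 1L,
    row_min = row_min, row_max = row_max,
    col_min = pmax(1L, ent_left - margin),
    col_max = ent_left + L_px + margin)
  right <- data.frame(
    channel_index = seq_len(n), side = "right",
    entrance_row = row_center, entrance_col = ent_right, axis = -1L,
    row_min = row_min, row_max = row_max,
    col_min = ent_right - L_px - margin,
    col_max = pmin(cols_img, ent_right + margin))
  rois <- rbind(left, right)
  if (any(rois$col_min < 1L) || any(rois$col_max > cols_img))
    stop("channel ROIs exceed image bounds; check geometry", call. = FALSE)
  rois
}

# Binary template of channel interiors (migration + main + central channels),
# used for bright-field rendering and for translation registration.
channel_template <- function(geometry) {
  g <- geometry
  px <- g$pixel_size_um
  rows <- g$image_shape_px[[1]]
  cols <- g$image_shape_px[[2]]
  main_px <- round(g$main_channel_width_um / px)
  L_px <- round(g$channel_length_um / px)
  tmpl <- matrix(FALSE, rows, cols)
  tmpl[, seq_len(main_px)] <- TRUE                      # left main
  tmpl[, (cols - main_px + 1L):cols] <- TRUE            # right main
  tmpl[, (main_px + L_px + 1L):(cols - main_px - L_px)] <- TRUE  # central
  rois <- channel_rois(g)
  half_w <- floor(g$channel_width_um / px / 2)
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    if (r$axis > 0) {
      c0 <- r$entrance_col + 1L; c1 <- r$entrance_col + L_px
    } else {
      c0 <- r$entrance_col - L_px; c1 <- r$entrance_col - 1L
    }
    tmpl[max(1L, r$entrance_row - half_w):min(rows, r$entrance_row + half_w),
         c0:c1] <- TRUE
  }
  tmpl
}

#' Indices of the central analysis window
#'
#' The channels retained for analysis are those nearest the midline of each
#' side's channel array (by default the central 300 of 450 channels per
#' side), where loading and gradient conditions are most uniform.
#'
#' @param n_channels_per_side Channels on one side.
#' @param central_window Number of channels per side to retain.
#' @return Integer vector of retained channel indices (1-based, per side).
#' @examples
#' range(central_window_indices(450, 300))  # 76 ... 375
#' @export
central_window_indices <- function(n_channels_per_side, central_window) {
  stopifnot(central_window >= 1,
            central_window <= n_channels_per_side)
  lo <- floor((n_channels_per_side - central_window) / 2) + 1L
  seq.int(lo, lo + central_window - 1L)
}

#' Serialize / read device geometry as JSON
#'
#' @param geometry A [device_geometry()].
#' @param path File path.
#' @return `read_geometry_json` returns a `device_geometry`;
#'   `write_geometry_json` returns `path` invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  x <- unclass(geometry)
  x$image_shape_px <- NULL  # derived; recomputed on read
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(device_geometry, x[setdiff(names(x), "image_shape_px")])
}
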