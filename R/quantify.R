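#' Quantification configuration
#'
#' Tuning parameters of the automated cell-counting pipeline. A pixel is
#' "bright" when its intensity strictly exceeds the plane's threshold; a
#' connected block of at least `min_bright_pixels` bright pixels is called
#' as one cell, which excludes noise, debris and device defects by their
#' small size or low intensity. The default minimum of 20 pixels at
#' 1 um/px is well below the ~78-pixel footprint of a 10-um cell while
#' comfortably above speckle noise.
#'
#' @param live_threshold,dead_threshold Intensity thresholds (0-255) for
#'   the live (FITC) and dead (TRITC) planes.
#' @param min_bright_pixels Minimum bright-pixel count of a valid cell.
#' @param pixel_size_um Pixel calibration used to convert distances to um.
#' @param central_window Channels per side retained for analysis
#'   (default 300 of 450), centered on the array midline.
#' @param connectivity Pixel connectivity for component labeling, 4 or 8.
#' @return Object of class `quant_config`.
#' @export
quant_config <- function(live_threshold = 50,
                         dead_threshold = 50,
                         min_bright_pixels = 20L,
                         pixel_size_um = 1,
                         central_window = 300L,
                         connectivity = 8L) {
  stopifnot(live_threshold >= 0, live_threshold <= 255,
            dead_threshold >= 0, dead_threshold <= 255,
            min_bright_pixels >= 1, pixel_size_um > 0,
            central_window >= 1, connectivity %in% c(4L, 8L))
  structure(list(live_threshold = live_threshold,
                 dead_threshold = dead_threshold,
                 min_bright_pixels = as.integer(min_bright_pixels),
                 pixel_size_um = pixel_size_um,
                 central_window = as.integer(central_window),
                 connectivity = as.integer(connectivity)),
            class = "quant_config")
}

#' Import a chip image from TIFF
#'
#' Reads a 1- or 3-page 8-bit grayscale TIFF into the three named planes
#' used by the pipeline. Three pages are taken in the order bright field,
#' live (FITC), dead (TRITC), as written by [write_device_image()]. A
#' single-page file is treated as the live plane with blank companions
#' (with a warning).
#'
#' @param path TIFF file path.
#' @return A `rendered_image` (integer matrices `bright_field`,
#'   `live_fluor`, `dead_fluor`).
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e) stop("unreadable TIFF: ",
                                             conditionMessage(e),
                                             call. = FALSE))
  bits <- vapply(pages, function(p) attr(p, "bits.per.sample") %||% NA_integer_,
                 integer(1))
  if (any(bits != 8L))
    stop("expected 8-bit TIFF, got ", paste(unique(bits), collapse = "/"),
         " bits per sample", call. = FALSE)
  strip <- function(p) matrix(as.integer(p), nrow(p), ncol(p))
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (length(pages) > 1 && any(dims != dims[, 1]))
    stop("TIFF pages have mismatched shapes", call. = FALSE)
  if (length(pages) == 3L) {
    out <- list(bright_field = strip(pages[[1]]),
                live_fluor = strip(pages[[2]]),
                dead_fluor = strip(pages[[3]]))
  } else if (length(pages) == 1L) {
    warning("single-page TIFF: treating it as the live plane", call. = FALSE)
    z <- matrix(0L, nrow(pages[[1]]), ncol(pages[[1]]))
    out <- list(bright_field = z, live_fluor = strip(pages[[1]]),
                dead_fluor = z)
  } else {
    stop("expected a 1- or 3-page TIFF, got ", length(pages), " pages",
         call. = FALSE)
  }
  class(out) <- "rendered_image"
  out
}

#' Segment migration channels
#'
#' Produces one rectangular region of interest per migration channel. The
#' chip layout is known by design, so segmentation is the geometry template,
#' optionally registered to the image by the integer translation that
#' maximizes the overlap between the template channel mask and the
#' bright-field plane (exhaustive search over `+/- max_shift` pixels).
#'
#' @param image A `rendered_image`.
#' @param geometry A [device_geometry()] consistent with the image shape.
#' @param registration `"none"` (template as-is) or `"translation"`.
#' @param max_shift Search half-window (pixels) for translation.
#' @return Data frame of channel ROIs as in [channel_rois()], shifted by
#'   the recovered offset, with the offset in `attr(,"offset")`.
#' @export
segment_channels <- function(image, geometry,
                             registration = c("none", "translation"),
                             max_shift = 10L) {
  registration <- match.arg(registration)
  stopifnot(inherits(image, "rendered_image"))
  sh <- dim(image$live_fluor)
  if (!all(sh == geometry$image_shape_px))
    stop("geometry image shape does not match the image", call. = FALSE)
  rois <- channel_rois(geometry)
  offset <- c(0L, 0L)
  if (registration == "translation") {
    tmpl <- channel_template(geometry)
    bf <- image$bright_field
    best <- -Inf
    for (dr in -max_shift:max_shift) {
      for (dc in -max_shift:max_shift) {
        score <- shifted_overlap(tmpl, bf, dr, dc)
        if (score > best) { best <- score; offset <- c(dr, dc) }
      }
    }
    rois$entrance_row <- rois$entrance_row + offset[1]
    rois$entrance_col <- rois$entrance_col + offset[2]
    rois$row_min <- rois$row_min + offset[1]
    rois$row_max <- rois$row_max + offset[1]
    rois$col_min <- rois$col_min + offset[2]
    rois$col_max <- rois$col_max + offset[2]
    if (any(rois$row_min < 1) || any(rois$row_max > sh[1]) ||
        any(rois$col_min < 1) || any(rois$col_max > sh[2]))
      stop("registered channel template exceeds image bounds", call. = FALSE)
  }
  attr(rois, "offset") <- offset
  rois
}

# Sum of image intensities under the template shifted by (dr, dc).
shifted_overlap <- function(tmpl, img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, 1L + dr); r1 <- min(nr, nr + dr)
  c0 <- max(1L, 1L + dc); c1 <- min(nc, nc + dc)
  if (r0 > r1 || c0 > c1) return(-Inf)
  sum(as.numeric(img[r0:r1, c0:c1]) *
        tmpl[(r0:r1) - dr, (c0:c1) - dc])
}

#' Threshold a plane into bright pixels
#'
#' A pixel is "bright" when its intensity strictly exceeds the threshold.
#'
#' @param plane 8-bit intensity matrix.
#' @param threshold Intensity threshold (0-255).
#' @return Logical matrix of the same shape.
#' @export
find_bright_pixels <- function(plane, threshold) {
  stopifnot(is.matrix(plane), threshold >= 0, threshold <= 255)
  plane > threshold
}

#' Label connected components of a binary mask
#'
#' Two-pass union-find labeling with 4- or 8-connectivity; labels are
#' consecutive integers from 1 in first-encounter order.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  id <- seq_along(idx)
  lookup <- matrix(0L, nr, nc)
  lookup[idx] <- id
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  parent <- id
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  offs <- list(c(-1L, 0L), c(0L, -1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L)))
  for (o in offs) {
    rr <- r + o[1]; ccn <- cc + o[2]
    ok <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
    nb <- lookup[cbind(rr[ok], ccn[ok])]
    has <- nb > 0L
    a <- id[ok][has]; b <- nb[has]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(id, find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Detect candidate cells within channel ROIs
#'
#' Labels connected components of the bright-pixel mask inside each channel
#' ROI. Components of at least `min_bright_pixels` pixels become detected
#' objects (initially class `"live"`, pending viability classification);
#' smaller components are kept with class `"rejected"` so that debris and
#' noise exclusions remain auditable.
#'
#' @param mask Logical bright-pixel matrix (typically the union of the
#'   live- and dead-plane masks).
#' @param config A [quant_config()].
#' @param rois Channel ROIs from [segment_channels()].
#' @return Data frame of objects: `channel_index`, `side`, `centroid_row`,
#'   `centroid_col` (global pixel coordinates), `bright_pixel_count`,
#'   `cls`, and a list-column `pixels` of global linear indices.
#' @export
detect_objects <- function(mask, config, rois) {
  stopifnot(is.matrix(mask), inherits(config, "quant_config"))
  nr <- nrow(mask)
  out <- list()
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    sub <- mask[roi$row_min:roi$row_max, roi$col_min:roi$col_max,
                drop = FALSE]
    if (!any(sub)) next
    lab <- label_components(sub, config$connectivity)
    ncomp <- max(lab)
    for (k in seq_len(ncomp)) {
      pix <- which(lab == k)
      pr <- ((pix - 1L) %% nrow(sub)) + roi$row_min
      pc <- ((pix - 1L) %/% nrow(sub)) + roi$col_min
      out[[length(out) + 1L]] <- data.frame(
        channel_index = roi$channel_index, side = roi$side,
        centroid_row = mean(pr), centroid_col = mean(pc),
        bright_pixel_count = length(pix),
        cls = if (length(pix) >= config$min_bright_pixels) "live"
              else "rejected",
        pixels = I(list(pr + (pc - 1L) * nr)))
    }
  }
  if (!length(out))
    return(data.frame(channel_index = integer(0), side = character(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      bright_pixel_count = integer(0), cls = character(0),
                      pixels = I(list())))
  do.call(rbind, out)
}

#' Classify detected objects as live or dead
#'
#' An accepted object is classed `"dead"` when its pixel footprint overlaps
#' at least one supra-threshold pixel of the dead (TRITC) plane, otherwise
#' `"live"`; rejected objects keep class `"rejected"`. Dead cells are
#' excluded from the migration frontier.
#'
#' @param objects Output of [detect_objects()].
#' @param live_mask,dead_mask Logical masks of the live and dead planes.
#' @return `objects` with `cls` updated.
#' @export
classify_viability <- function(objects, live_mask, dead_mask) {
  if (!nrow(objects)) return(objects)
  for (i in seq_len(nrow(objects))) {
    if (objects$cls[i] == "rejected") next
    objects$cls[i] <- if (any(dead_mask[objects$pixels[[i]]])) "dead"
                      else "live"
  }
  objects
}

#' Migration frontier of one channel
#'
#' The channel's migration distance is defined by the live cell that has
#' advanced farthest from the loading entrance: the along-axis component of
#' each live centroid, converted to micrometers and clamped to
#' `[0, channel_length]`. A channel with no live cells scores 0 (cells
#' remain at the loading position). Cells at or beyond the channel length
#' have reached the central channel.
#'
#' @param roi One-row ROI data frame (from [segment_channels()]).
#' @param objects Detected objects belonging to this channel.
#' @param config A [quant_config()].
#' @param channel_length_um Channel length L in micrometers.
#' @return One-row data frame: `channel_index`, `side`, `n_live`,
#'   `frontier_distance_um`, `reached_central`.
#' @export
channel_frontier <- function(roi, objects, config,
                             channel_length_um = 1000) {
  live <- objects[objects$cls == "live", , drop = FALSE]
  n_live <- nrow(live)
  d <- 0
  if (n_live > 0) {
    disp <- (live$centroid_col - roi$entrance_col) * roi$axis *
      config$pixel_size_um
    d <- max(pmin(pmax(disp, 0), channel_length_um))
  }
  data.frame(channel_index = roi$channel_index, side = roi$side,
             n_live = n_live, frontier_distance_um = d,
             reached_central = d >= channel_length_um - 1e-9)
}

#' Quantify a whole device image
#'
#' Runs the full automated analysis on a chip image: (1) channel
#' segmentation from the geometry template, (2) bright-pixel thresholding
#' of both fluorescence planes, (3) connected-component cell calling on the
#' union of the two masks, (4) exclusion of sub-minimum components (noise,
#' debris, defects) and of dead cells by their TRITC signal, and (5) the
#' per-channel migration frontier. Only the `central_window` channels per
#' side nearest the array midline are flagged for downstream analysis.
#'
#' @param image A `rendered_image` (or path handled by [load_image()]).
#' @param geometry A [device_geometry()].
#' @param config A [quant_config()].
#' @param registration Passed to [segment_channels()].
#' @param out_csv Optional path; when given, the per-channel table is also
#'   written as CSV.
#' @return Data frame with one row per channel: `channel_index`, `side`,
#'   `n_live`, `frontier_distance_um`, `reached_central`,
#'   `used_in_analysis`.
#' @export
quantify_device <- function(image, geometry, config = quant_config(),
                            registration = "none", out_csv = NULL) {
  if (is.character(image)) image <- load_image(image)
  if (config$central_window > geometry$n_channels_per_side)
    stop("central_window exceeds channels per side", call. = FALSE)
  rois <- segment_channels(image, geometry, registration)
  live_mask <- find_bright_pixels(image$live_fluor, config$live_threshold)
  dead_mask <- find_bright_pixels(image$dead_fluor, config$dead_threshold)
  objects <- detect_objects(live_mask | dead_mask, config, rois)
  objects <- classify_viability(objects, live_mask, dead_mask)
  keyed <- paste(objects$side, objects$channel_index)
  res <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    obj <- objects[keyed == paste(roi$side, roi$channel_index), ,
                   drop = FALSE]
    res[[i]] <- channel_frontier(roi, obj, config,
                                 geometry$channel_length_um)
  }
  res <- do.call(rbind, res)
  used <- central_window_indices(geometry$n_channels_per_side,
                                 config$central_window)
  res$used_in_analysis <- res$channel_index %in% used
  if (!is.null(out_csv)) utils::write.csv(res, out_csv, row.names = FALSE)
  res
}

#' Split channels into migratory and non-migratory populations
#'
#' Within the analysis window, a channel belongs to the migratory
#' population when its frontier cell reached the central channel, and to
#' the non-migratory population otherwise; the two sets partition the
#' analyzed channels.
#'
#' @param results Output of [quantify_device()].
#' @return List with data frames `migratory` and `non_migratory`.
#' @export
classify_populations <- function(results) {
  used <- results[results$used_in_analysis, , drop = FALSE]
  list(migratory = used[used$reached_central, , drop = FALSE],
       non_migratory = used[!used$reached_central, , drop = FALSE])
}

#' Count tumor spheres by diameter
#'
#' Counts single-cell-derived spheres on a fluorescence image of
#' sphere-chip wells. Connected supra-threshold components are measured by
#' their equivalent-area diameter, `2 * sqrt(area / pi) * pixel_size_um`;
#' only spheres larger than `min_diameter_um` (40 um by convention) count
#' as sphere-formation events.
#'
#' @param plane 8-bit intensity matrix.
#' @param threshold Intensity threshold.
#' @param pixel_size_um Pixel calibration.
#' @param min_diameter_um Minimum sphere diameter counted (default 40 um).
#' @param n_seeded_wells Number of wells seeded with single cells
#'   (denominator of the sphere-formation rate).
#' @param connectivity Component connectivity (default 8).
#' @return Object of class `sphere_count`: list with `n_spheres`,
#'   `sphere_rate`, `n_seeded_wells`, and the vector `diameters_um` of all
#'   component diameters.
#' @export
count_spheres <- function(plane, threshold, pixel_size_um = 1,
                          min_diameter_um = 40, n_seeded_wells,
                          connectivity = 8L) {
  if (missing(n_seeded_wells) || n_seeded_wells <= 0)
    stop("n_seeded_wells must be a positive count", call. = FALSE)
  lab <- label_components(find_bright_pixels(plane, threshold), connectivity)
  areas <- tabulate(lab[lab > 0L])
  diam <- 2 * sqrt(areas / pi) * pixel_size_um
  n <- sum(diam > min_diameter_um)
  structure(list(n_spheres = n, sphere_rate = n / n_seeded_wells,
                 n_seeded_wells = n_seeded_wells, diameters_um = diam),
            class = "sphere_count")
}

#' @export
print.sphere_count <- function(x, ...) {
  cat(sprintf("%d spheres above cutoff / %d seeded wells (rate %.3f)\n",
              x$n_spheres, x$n_seeded_wells, x$sphere_rate))
  invisible(x)
}
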