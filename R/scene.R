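#' Linear chemoattractant gradient along a migration channel
#'
#' At steady state, one-dimensional diffusion between two reservoirs held at
#' fixed concentrations gives an exactly linear profile along the channel.
#' Serum in the central channel and serum-free medium in the side channels
#' therefore produce a concentration that rises linearly from the loading
#' entrance (`x = 0`) to the central channel (`x = L`).
#'
#' @param c_central Concentration at the central-channel end (any unit).
#' @param c_side Concentration at the loading-side end.
#' @param x_um Position(s) along the channel, in micrometers from the
#'   loading entrance; must lie in `[0, L_um]`.
#' @param L_um Channel length in micrometers (> 0).
#' @return Concentration at `x_um`, same unit as the boundary values.
#' @examples
#' linear_gradient(5, 0, 500, 1000)  # 2.5
#' @export
linear_gradient <- function(c_central, c_side, x_um, L_um) {
  if (!is.finite(L_um) || L_um <= 0)
    stop("L_um must be positive", call. = FALSE)
  if (any(x_um < 0 | x_um > L_um))
    stop("x_um must lie within [0, L_um]", call. = FALSE)
  c_side + (c_central - c_side) * (x_um / L_um)
}

# Run code with an isolated, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_distances <- function(n, distance_dist, dist_params, L, px) {
  snap <- function(d) round(d / px) * px
  migratory <- rep(FALSE, n)
  d <- switch(distance_dist,
    point_mass_at_entrance = rep(0, n),
    uniform = {
      lo <- dist_params$min_um %||% 0
      hi <- dist_params$max_um %||% L
      snap(stats::runif(n, lo, hi))
    },
    exponential = {
      m <- dist_params$mean_um %||% 200
      snap(pmin(stats::rexp(n, rate = 1 / m), L))
    },
    two_component = {
      p <- dist_params$migratory_fraction %||% 0.1
      m <- dist_params$mean_um %||% 200
      migratory <- stats::runif(n) < p
      out <- rep(L, n)
      for (i in which(!migratory)) {
        # non-migratory component strictly inside the channel
        for (tr in 1:1000) {
          di <- snap(stats::rexp(1, rate = 1 / m))
          if (di < L) break
        }
        out[i] <- di
      }
      out
    },
    stop("unknown distance distribution: ", distance_dist, call. = FALSE)
  )
  list(distance_um = d, migratory = migratory)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a ground-truthed synthetic chip scene
#'
#' Places `n_cells` virtual cells on the migration chip with known channel
#' assignments, migration distances, viability, sizes and fluorescence
#' intensities, plus optional sub-detection debris objects. The scene is the
#' ground truth against which the automated quantification pipeline can be
#' benchmarked. Cell positions are snapped to the pixel grid (centers on
#' whole pixels) and cells within a channel are rejection-sampled so that
#' their rendered footprints never overlap.
#'
#' @param geometry A [device_geometry()].
#' @param n_cells Number of cells to place.
#' @param distance_dist Migration-distance distribution: one of
#'   `"point_mass_at_entrance"` (all cells at the loading entrance),
#'   `"uniform"` (`min_um`, `max_um`), `"exponential"` (`mean_um`, values
#'   beyond the channel length score as reaching the central channel), or
#'   `"two_component"` (`migratory_fraction` of cells traverse the full
#'   channel; the rest follow a truncated exponential with `mean_um`).
#' @param dist_params Named list of distribution parameters (see above).
#' @param dead_fraction Probability that a cell is dead (TRITC-positive).
#' @param debris_count Number of debris objects: small dim spots whose
#'   supra-threshold footprint stays below the cell-calling minimum.
#' @param noise_sd Gaussian read-noise standard deviation (intensity units)
#'   applied at render time.
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   scene exactly. The caller's RNG state is left untouched.
#' @param peak_range Range of per-cell peak fluorescence intensities
#'   (sampled uniformly as integers; keep above the detection threshold).
#' @param radius_range_um Cell radius range; the default corresponds to the
#'   10-15 um diameter of mammalian cancer cells.
#' @param max_tries Placement attempts per object before declaring the
#'   packing infeasible.
#' @return An object of class `synthetic_scene`: list with `geometry`,
#'   `cells` (data frame: `channel_index`, `side`, `distance_um`,
#'   `viability`, `radius_um`, `peak_intensity`, `migratory`), `debris`
#'   (data frame of positions and radii), `noise_sd`, `seed`, and the
#'   sampling parameters.
#' @export
sample_scene <- function(geometry, n_cells,
                         distance_dist = "two_component",
                         dist_params = list(),
                         dead_fraction = 0,
                         debris_count = 0,
                         noise_sd = 0,
                         seed = 1L,
                         peak_range = c(120L, 220L),
                         radius_range_um = c(5, 7.5),
                         max_tries = 200L) {
  stopifnot(inherits(geometry, "device_geometry"),
            n_cells >= 0, debris_count >= 0,
            dead_fraction >= 0, dead_fraction <= 1,
            noise_sd >= 0)
  px <- geometry$pixel_size_um
  L <- geometry$channel_length_um
  n_side <- geometry$n_channels_per_side
  debris_radius_um <- 2 * px  # ~12.6 px^2 footprint at 1 um/px, < 20-px minimum

  scene <- with_seed(seed, {
    cells <- data.frame(channel_index = integer(0), side = character(0),
                        distance_um = numeric(0), viability = character(0),
                        radius_um = numeric(0), peak_intensity = integer(0),
                        migratory = logical(0))
    # per-channel occupied intervals (positions and radii, px units)
    occ <- new.env(parent = emptyenv())
    key <- function(side, idx) paste0(side, idx)
    fits <- function(side, idx, pos_px, r_px) {
      k <- key(side, idx)
      prev <- occ[[k]]
      if (is.null(prev)) return(TRUE)
      all(abs(prev$pos - pos_px) >= prev$r + r_px + 3)
    }
    push <- function(side, idx, pos_px, r_px) {
      k <- key(side, idx)
      prev <- occ[[k]] %||% list(pos = numeric(0), r = numeric(0))
      occ[[k]] <- list(pos = c(prev$pos, pos_px), r = c(prev$r, r_px))
    }

    if (n_cells > 0) {
      ds <- sample_distances(n_cells, distance_dist, dist_params, L, px)
      viab <- ifelse(stats::runif(n_cells) < dead_fraction, "dead", "live")
      radii <- stats::runif(n_cells, radius_range_um[1], radius_range_um[2])
      peaks <- as.integer(round(stats::runif(n_cells, peak_range[1],
                                             peak_range[2])))
      sides <- character(n_cells); chans <- integer(n_cells)
      dists <- ds$distance_um
      for (i in seq_len(n_cells)) {
        placed <- FALSE
        r_px <- radii[i] / px
        for (tr in seq_len(max_tries)) {
          side <- if (stats::runif(1) < 0.5) "left" else "right"
          idx <- sample.int(n_side, 1)
          pos_px <- round(dists[i] / px)
          if (fits(side, idx, pos_px, r_px)) {
            push(side, idx, pos_px, r_px)
            sides[i] <- side; chans[i] <- idx
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("infeasible packing: could not place cell ", i,
               " after ", max_tries, " tries", call. = FALSE)
      }
      cells <- data.frame(channel_index = chans, side = sides,
                          distance_um = dists, viability = viab,
                          radius_um = radii, peak_intensity = peaks,
                          migratory = ds$migratory)
    }

    debris <- data.frame(channel_index = integer(0), side = character(0),
                         distance_um = numeric(0), radius_um = numeric(0),
                         peak_intensity = integer(0))
    if (debris_count > 0) {
      r_px <- debris_radius_um / px
      for (i in seq_len(debris_count)) {
        placed <- FALSE
        for (tr in seq_len(max_tries)) {
          side <- if (stats::runif(1) < 0.5) "left" else "right"
          idx <- sample.int(n_side, 1)
          pos_px <- round(stats::runif(1, 0, L) / px)
          if (fits(side, idx, pos_px, r_px)) {
            push(side, idx, pos_px, r_px)
            debris[i, ] <- list(idx, side, pos_px * px, debris_radius_um,
                                as.integer(round(stats::runif(1, 80, 150))))
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("infeasible packing: could not place debris ", i, call. = FALSE)
      }
    }
    list(cells = cells, debris = debris)
  })

  out <- list(geometry = geometry, cells = scene$cells, debris = scene$debris,
              debris_count = as.integer(debris_count), noise_sd = noise_sd,
              seed = as.integer(seed),
              params = list(n_cells = n_cells, distance_dist = distance_dist,
                            dist_params = dist_params,
                            dead_fraction = dead_fraction,
                            peak_range = peak_range,
                            radius_range_um = radius_range_um))
  class(out) <- "synthetic_scene"
  out
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic chip scene: %d cells (%d dead), %d debris, noise sd %g, seed %d\n",
              nrow(x$cells), sum(x$cells$viability == "dead"),
              nrow(x$debris), x$noise_sd, x$seed))
  invisible(x)
}

# Additively draw an anti-aliased disk into a numeric matrix (max overlay).
# Core (dist <= r - 0.5) at full intensity, 1-px linear rim.
draw_disk <- function(mat, row, col, r_px, intensity) {
  R <- ceiling(r_px + 0.5)
  rows <- max(1L, row - R):min(nrow(mat), row + R)
  cols <- max(1L, col - R):min(ncol(mat), col + R)
  dr <- rows - row
  dc <- cols - col
  dist <- sqrt(outer(dr^2, dc^2, `+`))
  val <- intensity * pmin(1, pmax(0, r_px + 0.5 - dist))
  mat[rows, cols] <- pmax(mat[rows, cols], val)
  mat
}

cell_center_px <- function(geometry, side, channel_index, distance_um,
                           rois = channel_rois(geometry)) {
  px <- geometry$pixel_size_um
  m <- match(paste(side, channel_index),
             paste(rois$side, rois$channel_index))
  r <- rois[m, , drop = FALSE]
  d_px <- round(distance_um / px)
  cbind(row = r$entrance_row, col = r$entrance_col + r$axis * d_px)
}

#' Render a synthetic scene to a multi-plane chip image
#'
#' Draws every ground-truth object as a hard disk with a one-pixel
#' anti-aliased rim: live cells into the live (FITC) plane, dead cells into
#' the dead (TRITC) plane, and all cells plus the channel layout into the
#' bright-field plane. Gaussian read noise of standard deviation
#' `scene$noise_sd` is then added to every plane and intensities are rounded
#' and clipped to the 8-bit range. Rendering is deterministic given the
#' scene's seed.
#'
#' @param scene A [sample_scene()] result.
#' @param bright_field_channels If `TRUE` (default) the bright-field plane
#'   shows the channel interiors at a low uniform intensity, as a real
#'   transmitted-light image of the device would; set `FALSE` for a blank
#'   bright-field background.
#' @return An object of class `rendered_image`: list of integer matrices
#'   `bright_field`, `live_fluor`, `dead_fluor`, all of
#'   `geometry$image_shape_px`, values in 0-255.
#' @export
render_scene <- function(scene, bright_field_channels = TRUE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  g <- scene$geometry
  px <- g$pixel_size_um
  rows <- g$image_shape_px[[1]]; cols <- g$image_shape_px[[2]]
  live <- matrix(0, rows, cols)
  dead <- matrix(0, rows, cols)
  bf <- if (bright_field_channels) channel_template(g) * 80 else
    matrix(0, rows, cols)
  rois <- channel_rois(g)

  cells <- scene$cells
  for (i in seq_len(nrow(cells))) {
    ctr <- cell_center_px(g, cells$side[i], cells$channel_index[i],
                          cells$distance_um[i], rois)
    r_px <- cells$radius_um[i] / px
    if (cells$viability[i] == "live")
      live <- draw_disk(live, ctr[1, "row"], ctr[1, "col"], r_px,
                        cells$peak_intensity[i])
    else
      dead <- draw_disk(dead, ctr[1, "row"], ctr[1, "col"], r_px,
                        cells$peak_intensity[i])
    bf <- draw_disk(bf, ctr[1, "row"], ctr[1, "col"], r_px, 150)
  }
  deb <- scene$debris
  for (i in seq_len(nrow(deb))) {
    ctr <- cell_center_px(g, deb$side[i], deb$channel_index[i],
                          deb$distance_um[i], rois)
    r_px <- deb$radius_um[i] / px
    live <- draw_disk(live, ctr[1, "row"], ctr[1, "col"], r_px,
                      deb$peak_intensity[i])
    bf <- draw_disk(bf, ctr[1, "row"], ctr[1, "col"], r_px, 120)
  }

  if (scene$noise_sd > 0) {
    noise_seed <- (scene$seed + 104729L) %% 2147483647L
    noise <- with_seed(noise_seed, {
      list(bf = stats::rnorm(length(bf), 0, scene$noise_sd),
           live = stats::rnorm(length(live), 0, scene$noise_sd),
           dead = stats::rnorm(length(dead), 0, scene$noise_sd))
    })
    bf <- bf + noise$bf; live <- live + noise$live; dead <- dead + noise$dead
  }
  clip8 <- function(m) {
    m <- matrix(as.integer(pmin(255, pmax(0, round(m)))), nrow(m), ncol(m))
    m
  }
  out <- list(bright_field = clip8(bf), live_fluor = clip8(live),
              dead_fluor = clip8(dead))
  class(out) <- "rendered_image"
  out
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("Rendered chip image: %d x %d px, 3 planes (bright_field, live_fluor, dead_fluor)\n",
              nrow(x$live_fluor), ncol(x$live_fluor)))
  invisible(x)
}

#' Per-channel ground truth of a synthetic scene
#'
#' Summarizes the generator's ground truth per migration channel: live-cell
#' census and the true migration frontier (the farthest live cell, 0 when
#' the channel holds no live cell), for direct comparison against the
#' automated pipeline's [quantify_device()] output.
#'
#' @param scene A [sample_scene()] result.
#' @return Data frame with `channel_index`, `side`, `n_live`, `n_dead`,
#'   `frontier_distance_um`, `reached_central`.
#' @export
scene_channel_truth <- function(scene) {
  g <- scene$geometry
  rois <- channel_rois(g)
  out <- rois[, c("channel_index", "side")]
  out$n_live <- 0L; out$n_dead <- 0L
  out$frontier_distance_um <- 0
  cells <- scene$cells
  if (nrow(cells)) {
    k <- paste(cells$side, cells$channel_index)
    ko <- paste(out$side, out$channel_index)
    for (i in seq_len(nrow(out))) {
      sel <- k == ko[i]
      live <- sel & cells$viability == "live"
      out$n_live[i] <- sum(live)
      out$n_dead[i] <- sum(sel) - out$n_live[i]
      if (any(live))
        out$frontier_distance_um[i] <- max(cells$distance_um[live])
    }
  }
  out$reached_central <- out$frontier_distance_um >= g$channel_length_um
  out
}

#' Write / read chip images and ground truth
#'
#' `write_device_image` writes a [render_scene()] result as a 3-page 8-bit
#' grayscale TIFF (page order: bright field, live/FITC, dead/TRITC).
#' `write_ground_truth` writes the scene's cell table as CSV.
#'
#' @param image A `rendered_image`.
#' @param scene A `synthetic_scene`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_device_image <- function(image, path) {
  stopifnot(inherits(image, "rendered_image"))
  pages <- list(image$bright_field, image$live_fluor, image$dead_fluor)
  tiff::writeTIFF(lapply(pages, function(m) m / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_device_image
#' @export
write_ground_truth <- function(scene, path) {
  stopifnot(inherits(scene, "synthetic_scene"))
  utils::write.csv(scene$cells[, c("channel_index", "side", "distance_um",
                                   "viability", "radius_um",
                                   "peak_intensity")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Render free-standing disks into a plane
#'
#' Small utility for building single-plane fluorescence fixtures (for
#' example, sphere-formation well images): draws anti-aliased disks of the
#' given radii at the given centers on a dark background.
#'
#' @param shape_px `c(rows, cols)` of the output plane.
#' @param centers_px Two-column matrix of disk centers (row, col).
#' @param radii_px Disk radii in pixels (recycled).
#' @param intensity Peak intensity (0-255).
#' @return Integer matrix with values in 0-255.
#' @export
render_disks <- function(shape_px, centers_px, radii_px, intensity = 200) {
  m <- matrix(0, shape_px[1], shape_px[2])
  radii_px <- rep_len(radii_px, nrow(centers_px))
  for (i in seq_len(nrow(centers_px)))
    m <- draw_disk(m, centers_px[i, 1], centers_px[i, 2], radii_px[i],
                   intensity)
  matrix(as.integer(pmin(255, pmax(0, round(m)))), nrow(m), ncol(m))
}
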