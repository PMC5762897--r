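make_device <- function(n = 8, n_cells = 20, seed = 3, ...) {
  g <- small_geometry(n)
  s <- sample_scene(g, n_cells, seed = seed, ...)
  list(g = g, s = s, img = render_scene(s))
}

test_that("TIFF import round-trips and rejects malformed input", {
  d <- make_device(4, 8, distance_dist = "uniform")
  f <- withr::local_tempfile(fileext = ".tif")
  write_device_image(d$img, f)
  img2 <- load_image(f)
  expect_identical(d$img$bright_field, img2$bright_field)
  expect_identical(d$img$live_fluor, img2$live_fluor)
  expect_identical(d$img$dead_fluor, img2$dead_fluor)

  f16 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), f16, bits.per.sample = 16L)
  expect_error(load_image(f16), "8-bit")

  f1 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(d$img$live_fluor / 255, f1, bits.per.sample = 8L)
  expect_warning(img1 <- load_image(f1), "single-page")
  expect_identical(img1$live_fluor, d$img$live_fluor)
  expect_true(all(img1$dead_fluor == 0L))

  expect_error(load_image(withr::local_tempfile()), "no such file")
})

test_that("channel segmentation recovers a translated template", {
  d <- make_device(8, 30, distance_dist = "uniform", seed = 2)
  rois0 <- segment_channels(d$img, d$g, "none")
  expect_equal(nrow(rois0), 16L)
  expect_equal(attr(rois0, "offset"), c(0L, 0L))
  expect_equal(rois0[, setdiff(names(rois0), "offset")],
               channel_rois(d$g), ignore_attr = TRUE)

  shifted <- shift_image(d$img, 3, -5)
  rois <- segment_channels(shifted, d$g, "translation")
  expect_equal(attr(rois, "offset"), c(3L, -5L))
  # registered ROIs line up with the shifted cells: re-quantify exactly
  cfg <- quant_config(central_window = 8)
  res <- quantify_device(shifted, d$g, cfg, registration = "translation")
  truth <- scene_channel_truth(d$s)
  expect_equal(res$frontier_distance_um, truth$frontier_distance_um)

  expect_error(segment_channels(d$img, small_geometry(5)), "shape")
})

test_that("bright-pixel rule uses a strict inequality", {
  p <- matrix(0L, 4, 4)
  expect_false(any(find_bright_pixels(p, 50)))
  expect_true(all(find_bright_pixels(matrix(255L, 2, 2), 254)))
  p[2, 2] <- 50L
  expect_false(find_bright_pixels(p, 50)[2, 2])
  p[2, 2] <- 51L
  expect_true(find_bright_pixels(p, 50)[2, 2])
})

test_that("component labelling agrees with an independent flood-fill oracle", {
  set.seed(42)
  for (conn in c(4L, 8L)) {
    for (rep in 1:5) {
      mask <- matrix(runif(30 * 40) < 0.35, 30, 40)
      ours <- label_components(mask, conn)
      ref <- bfs_label(mask, conn)
      expect_equal(max(ours), max(ref))
      # same partition: label images are equal up to renaming
      expect_equal(length(unique(paste(ours[mask], ref[mask]))),
                   max(ref))
    }
  }
  expect_equal(max(label_components(matrix(FALSE, 3, 3), 8L)), 0)
})

test_that("object detection applies the minimum-bright-pixel rule per channel", {
  g <- small_geometry(6)
  rois <- channel_rois(g)
  cfg <- quant_config(min_bright_pixels = 10, central_window = 6)
  mask <- matrix(FALSE, g$image_shape_px[1], g$image_shape_px[2])
  expect_equal(nrow(detect_objects(mask, cfg, rois)), 0L)

  # one 30-pixel blob inside channel 2 (left), one 4-pixel blob in channel 3
  r2 <- rois[rois$side == "left" & rois$channel_index == 2, ]
  mask[r2$entrance_row + (-2:2), r2$entrance_col + (100:105)] <- TRUE
  r3 <- rois[rois$side == "left" & rois$channel_index == 3, ]
  mask[r3$entrance_row + (0:1), r3$entrance_col + (50:51)] <- TRUE
  obj <- detect_objects(mask, cfg, rois)
  expect_equal(nrow(obj), 2L)
  accepted <- obj[obj$cls != "rejected", ]
  expect_equal(accepted$bright_pixel_count, 30L)
  expect_equal(accepted$channel_index, 2)
  expect_equal(obj$cls[obj$channel_index == 3], "rejected")

  # exactly at the minimum counts as a cell; one below does not
  cfg30 <- quant_config(min_bright_pixels = 30, central_window = 6)
  expect_equal(sum(detect_objects(mask, cfg30, rois)$cls != "rejected"), 1L)
  cfg31 <- quant_config(min_bright_pixels = 31, central_window = 6)
  expect_equal(sum(detect_objects(mask, cfg31, rois)$cls != "rejected"), 0L)
})

test_that("detection excludes debris and recovers the planted cell count", {
  d <- make_device(10, 50, seed = 9, distance_dist = "uniform",
                   debris_count = 20)
  cfg <- quant_config(central_window = 10)
  rois <- segment_channels(d$img, d$g)
  mask <- find_bright_pixels(d$img$live_fluor, cfg$live_threshold)
  obj <- detect_objects(mask, cfg, rois)
  expect_equal(sum(obj$cls != "rejected"), 50L)
})

test_that("viability classification matches the generator's dead fraction", {
  d <- make_device(10, 60, seed = 21, distance_dist = "uniform",
                   dead_fraction = 0.3)
  cfg <- quant_config(central_window = 10)
  rois <- segment_channels(d$img, d$g)
  live_mask <- find_bright_pixels(d$img$live_fluor, cfg$live_threshold)
  dead_mask <- find_bright_pixels(d$img$dead_fluor, cfg$dead_threshold)
  obj <- detect_objects(live_mask | dead_mask, cfg, rois)
  obj <- classify_viability(obj, live_mask, dead_mask)
  expect_equal(sum(obj$cls == "dead"),
               sum(d$s$cells$viability == "dead"))
  expect_equal(sum(obj$cls == "live"),
               sum(d$s$cells$viability == "live"))

  # all-dead scene: every channel reports zero live cells
  dd <- make_device(6, 12, seed = 4, distance_dist = "uniform",
                    dead_fraction = 1)
  res <- quantify_device(dd$img, dd$g, quant_config(central_window = 6))
  expect_true(all(res$n_live == 0))
  expect_true(all(res$frontier_distance_um == 0))
})

test_that("channel frontier takes the farthest live centroid, clamped to the channel", {
  g <- small_geometry(4)
  roi <- channel_rois(g)[1, ]
  cfg <- quant_config(central_window = 4)
  none <- data.frame(channel_index = integer(0), side = character(0),
                     centroid_row = numeric(0), centroid_col = numeric(0),
                     bright_pixel_count = integer(0), cls = character(0))
  r <- channel_frontier(roi, none, cfg, 1000)
  expect_equal(r$frontier_distance_um, 0)
  expect_false(r$reached_central)

  obj <- data.frame(channel_index = 1, side = "left",
                    centroid_row = roi$entrance_row,
                    centroid_col = roi$entrance_col + 300,
                    bright_pixel_count = 60L, cls = "live")
  expect_equal(channel_frontier(roi, obj, cfg, 1000)$frontier_distance_um, 300)

  # a cell at the channel exit reaches the central channel
  obj$centroid_col <- roi$entrance_col + 1000
  r <- channel_frontier(roi, obj, cfg, 1000)
  expect_equal(r$frontier_distance_um, 1000)
  expect_true(r$reached_central)

  # frontier is invariant to adding a live cell strictly behind it
  behind <- obj; behind$centroid_col <- roi$entrance_col + 120
  r2 <- channel_frontier(roi, rbind(obj, behind), cfg, 1000)
  expect_equal(r2$frontier_distance_um, 1000)
  # dead cells are excluded from the frontier
  deadfront <- obj; deadfront$cls <- "dead"
  r3 <- channel_frontier(roi, rbind(behind, deadfront), cfg, 1000)
  expect_equal(r3$frontier_distance_um, 120)
})

test_that("whole-device quantification flags the central analysis window", {
  # default 900-channel geometry at coarse pixel size: 600 channels analyzed
  g <- device_geometry(pixel_size_um = 4)
  blank <- render_scene(sample_scene(g, 0, seed = 1))
  res <- quantify_device(blank, g, quant_config(pixel_size_um = 4))
  expect_equal(nrow(res), 900L)
  expect_equal(sum(res$used_in_analysis), 600L)
  expect_equal(sort(unique(res$channel_index[res$used_in_analysis])), 76:375)

  expect_equal(central_window_indices(450, 450), 1:450)
  expect_error(central_window_indices(450, 451), "central_window")
})

test_that("population split partitions analyzed channels by central arrival", {
  d <- make_device(30, 150, seed = 31, distance_dist = "two_component",
                   dist_params = list(migratory_fraction = 0.2,
                                      mean_um = 250))
  cfg <- quant_config(central_window = 20)
  res <- quantify_device(d$img, d$g, cfg)
  pops <- classify_populations(res)
  used <- res[res$used_in_analysis, ]
  expect_equal(nrow(pops$migratory) + nrow(pops$non_migratory), nrow(used))
  expect_length(intersect(rownames(pops$migratory),
                          rownames(pops$non_migratory)), 0)
  truth <- scene_channel_truth(d$s)
  key <- function(df) paste(df$side, df$channel_index)
  expect_setequal(key(pops$migratory),
                  intersect(key(used), key(truth[truth$reached_central, ])))

  # all distances zero: no migratory channels
  d0 <- make_device(6, 5, seed = 2, distance_dist = "point_mass_at_entrance")
  res0 <- quantify_device(d0$img, d0$g, quant_config(central_window = 6))
  expect_equal(nrow(classify_populations(res0)$migratory), 0L)
})

test_that("raising thresholds or the size minimum never adds detections", {
  d <- make_device(8, 30, seed = 17, distance_dist = "uniform",
                   noise_sd = 8, debris_count = 10)
  rois <- segment_channels(d$img, d$g)
  n_at <- function(thr, mbp) {
    cfg <- quant_config(live_threshold = thr, min_bright_pixels = mbp,
                        central_window = 8)
    sum(detect_objects(find_bright_pixels(d$img$live_fluor, thr),
                       cfg, rois)$cls != "rejected")
  }
  counts_thr <- vapply(c(30, 50, 80, 120, 180, 240), n_at,
                       numeric(1), mbp = 20)
  expect_true(all(diff(counts_thr) <= 0))
  counts_mbp <- vapply(c(5, 10, 20, 40, 80, 200), function(m) n_at(50, m),
                       numeric(1))
  expect_true(all(diff(counts_mbp) <= 0))
})

test_that("sphere counting applies the 40-um diameter rule", {
  mk <- function(diams_um) {
    n <- length(diams_um)
    centers <- cbind(60 + 110 * (seq_len(n) - 1) %/% 5 * 1,
                     60 + 110 * ((seq_len(n) - 1) %% 5))
    render_disks(c(600, 600), centers, diams_um / 2, intensity = 200)
  }
  one45 <- mk(45)
  expect_equal(count_spheres(one45, 50, 1, 40, n_seeded_wells = 10)$n_spheres,
               1L)
  one35 <- mk(35)
  expect_equal(count_spheres(one35, 50, 1, 40, n_seeded_wells = 10)$n_spheres,
               0L)
  set.seed(8)
  diams <- sample(c(25:36, 44:60), 20, replace = TRUE)
  sc <- count_spheres(mk(diams), 50, 1, 40, n_seeded_wells = 100)
  expect_equal(sc$n_spheres, sum(diams > 40))
  expect_equal(sc$sphere_rate, sum(diams > 40) / 100)
  # measured diameters track the drawn ones
  expect_equal(sort(sc$diameters_um), sort(diams), tolerance = 0.05)
  expect_error(count_spheres(one45, 50, 1, 40, n_seeded_wells = 0),
               "positive")
})
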