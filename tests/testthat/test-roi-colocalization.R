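test_that("tROI side is 115% of the fitted major axis", {
  # ellipse with 200 um major axis at 1 um/px
  m <- raster_ellipse(100, 60, theta = 0.4, pad = 20)
  rois <- extract_spheroid_rois(binary_mask(m, 1), 500)
  expect_length(rois, 1)
  roi <- rois[[1]]
  expect_equal(roi$troi$side, 230, tolerance = 0.01)
  expect_equal(roi$ellipse$major_um, 200, tolerance = 0.01)
  # circular spheroid: side = 1.15 * d
  d <- raster_disk(50)
  roi_c <- extract_spheroid_rois(binary_mask(d, 1), 500)[[1]]
  expect_equal(roi_c$troi$side, round(1.15 * 100), tolerance = 1)
  expect_false(roi$clipped)
})

test_that("tROIs clip at image borders and empty masks yield empty lists", {
  m <- matrix(FALSE, 120, 120)
  m[30:70, 2:30] <- TRUE  # blob close to the left edge
  rois <- extract_spheroid_rois(binary_mask(m, 1), 100)
  expect_length(rois, 1)
  expect_true(rois[[1]]$clipped)
  expect_gte(rois[[1]]$troi$left, 1)
  expect_length(extract_spheroid_rois(binary_mask(matrix(FALSE, 10, 10), 1)), 0)
})

test_that("ellipse fits recover generating axes within 3 percent", {
  for (par in list(c(60, 40, 0), c(100, 50, 0.7), c(35, 30, 1.2))) {
    m <- raster_ellipse(par[1], par[2], par[3])
    roi <- extract_spheroid_rois(binary_mask(m, 1), 100)[[1]]
    expect_lt(abs(roi$ellipse$major_um - 2 * par[1]) / (2 * par[1]), 0.03)
    expect_lt(abs(roi$ellipse$minor_um - 2 * par[2]) / (2 * par[2]), 0.03)
  }
})

test_that("vessel ROI crops the mask and computes its area", {
  sph <- matrix(FALSE, 200, 200); sph[81:120, 81:120] <- TRUE
  troi <- extract_spheroid_rois(binary_mask(sph, 1), 100)[[1]]
  empty_v <- binary_mask(matrix(FALSE, 200, 200), 1)
  expect_equal(build_vessel_roi(empty_v, troi)$vessel_area_um2, 0)
  solid <- matrix(FALSE, 200, 200); solid[91:110, 91:110] <- TRUE
  vroi <- build_vessel_roi(binary_mask(solid, 1), troi)
  expect_equal(vroi$vessel_area_um2, 400)
  expect_equal(dim(vroi$mask$pixels),
               c(troi$troi$bottom - troi$troi$top + 1,
                 troi$troi$right - troi$troi$left + 1))
  expect_error(build_vessel_roi(binary_mask(solid, 2), troi), "calibration")
})

test_that("Otsu threshold maximizes between-class variance", {
  v <- c(rep(30, 950), rep(220, 50))
  ot <- otsu_threshold(v)
  expect_gt(ot$threshold, 30)
  expect_lt(ot$threshold, 220)
  # brute-force oracle: scan all integer thresholds and evaluate the
  # between-class variance directly from the data; the returned threshold
  # must attain the brute-force optimum (ties form plateaus)
  sb_of <- function(vals, t) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }
  set.seed(31)
  for (i in 1:10) {
    v <- round(c(rnorm(400, 70, 15), rnorm(100, 200, 12)))
    v <- pmax(v, 0)
    best_sb <- max(vapply(seq(min(v), max(v) - 1), function(t) sb_of(v, t),
                          numeric(1)))
    expect_equal(sb_of(v, otsu_threshold(v)$threshold), best_sb,
                 tolerance = 1e-9)
  }
  # independent cross-check: the reference implementation's threshold
  # attains the same criterion value
  e_thr <- 255 * EBImage::otsu(EBImage::Image(matrix(v / 255, 25)),
                               range = c(0, 1), levels = 256)
  expect_equal(sb_of(v, otsu_threshold(v)$threshold), sb_of(v, floor(e_thr)),
               tolerance = 1e-6)
  expect_warning(res <- otsu_threshold(rep(5, 10)), "constant")
  expect_true(is.na(res$threshold))
})

make_count_fixture <- function() {
  # 100x100 window: vessel band rows 20-60; 3 passing particles inside,
  # 2 outside; plus an undersized and an elongated distractor inside
  vessel <- matrix(FALSE, 100, 100)
  vessel[20:60, ] <- TRUE
  cancer <- matrix(40, 100, 100)
  stamp_disk <- function(img, r0, c0, n_px, value = 300) {
    off <- mvnquant:::compact_blob_offsets(n_px)
    img[cbind(r0 + off[, 1], c0 + off[, 2])] <- value
    img
  }
  cancer <- stamp_disk(cancer, 30, 20, 80)
  cancer <- stamp_disk(cancer, 45, 50, 100)
  cancer <- stamp_disk(cancer, 35, 80, 64)
  cancer <- stamp_disk(cancer, 75, 30, 80)   # outside vessel
  cancer <- stamp_disk(cancer, 80, 70, 90)   # outside vessel
  cancer <- stamp_disk(cancer, 52, 25, 49)   # undersized inside
  cancer[25, 40:69] <- 300                   # 1x30 line inside
  troi <- structure(list(
    spheroid_id = "sphX",
    ellipse = list(center_row = 50, center_col = 50, major_um = 87,
                   minor_um = 87, orientation = 0),
    troi = list(top = 1L, left = 1L, bottom = 100L, right = 100L,
                side = 100L),
    clipped = FALSE, pixel_size_um = 1), class = "spheroid_roi")
  vroi <- build_vessel_roi(binary_mask(vessel, 1), troi)
  list(cancer = calibrated_image(cancer, "cancer", 1), vroi = vroi,
       vessel = vessel)
}

test_that("event counting applies the masking, size and circularity filters", {
  fx <- make_count_fixture()
  ev <- count_intravasation_events(fx$cancer, fx$vroi)
  expect_equal(ev$n_events, 3)
  passed <- ev$particles[ev$particles$passed_filters, ]
  expect_true(all(passed$area_um2 >= 50))
  expect_true(all(passed$circularity >= 0.5 & passed$circularity <= 1))
  # the undersized and line distractors are present but filtered
  expect_gte(nrow(ev$particles), 4)
})

test_that("counting is invariant to cancer signal outside the vROI", {
  fx <- make_count_fixture()
  base <- count_intravasation_events(fx$cancer, fx$vroi)$n_events
  set.seed(41)
  for (i in 1:5) {
    repainted <- fx$cancer$pixels
    outside <- !fx$vroi$mask$pixels
    repainted[outside] <- sample(0:500, sum(outside), replace = TRUE)
    ev <- count_intravasation_events(
      calibrated_image(repainted, "cancer", 1), fx$vroi)
    expect_equal(ev$n_events, base)
  }
})

test_that("raising the filters never increases the event count", {
  fx <- make_count_fixture()
  base <- count_intravasation_events(fx$cancer, fx$vroi, 50, 0.5, 1.0)$n_events
  for (min_area in c(0, 50, 90, 200)) {
    wide <- count_intravasation_events(fx$cancer, fx$vroi, min_area, 0, 1)$n_events
    narrow <- count_intravasation_events(fx$cancer, fx$vroi, min_area, 0.6, 0.9)$n_events
    expect_lte(narrow, wide)
  }
  expect_lte(count_intravasation_events(fx$cancer, fx$vroi, 90, 0.5, 1)$n_events,
             base)
  expect_gte(count_intravasation_events(fx$cancer, fx$vroi, 0, 0.5, 1)$n_events,
             base)
})

test_that("planted-scene counting recovers ground truth", {
  sp <- scene_spec(seed = 77, n_intravascular = 3, n_extravascular = 2,
                   n_elongated = 1, n_undersized = 1, dropout_fraction = 0,
                   vessel_width_range_um = c(18, 40), tortuosity = 0.1)
  sc <- generate_scene(sp)
  vm <- morph_clean(default_threshold(sc$channels$gfp), 1, 1)
  trois <- extract_spheroid_rois(default_threshold(sc$channels$cancer), 500)
  expect_length(trois, 1)
  vroi <- build_vessel_roi(vm, trois[[1]])
  ev <- count_intravasation_events(crop_to_troi(sc$channels$cancer, trois[[1]]),
                                   vroi)
  expect_equal(ev$n_events, sc$truth$n_events)
})

test_that("event summaries aggregate per group", {
  mk <- function(id, n, grp) {
    structure(list(spheroid_id = id, n_events = n,
                   particles = data.frame(), condition_label = grp),
              class = "event_count")
  }
  counts <- list(mk("a", 0, "ctrl"), mk("b", 1, "ctrl"), mk("c", 2, "ctrl"),
                 mk("d", 3, "emt"))
  s <- summarize_events(counts)
  ctrl <- s$summary[s$summary$group == "ctrl", ]
  expect_equal(ctrl$mean_events, 1)
  expect_equal(ctrl$median_events, 1)
  expect_equal(ctrl$n_spheroids, 3)
  emt <- s$summary[s$summary$group == "emt", ]
  expect_true(is.na(emt$sd_events))
  # two identical groups produce identical summary rows
  s2 <- summarize_events(list(mk("a", 2, "g1"), mk("b", 4, "g1"),
                              mk("c", 2, "g2"), mk("d", 4, "g2")))
  r <- s2$summary
  expect_equal(r[r$group == "g1", -1], r[r$group == "g2", -1],
               ignore_attr = TRUE)
})
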