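test_that("phantom topologies reproduce hand-computed truth", {
  cases <- list(list("bar", 100), list("Y", 50), list("cross", 100),
                list("lattice", 100))
  for (cs in cases) {
    ph <- generate_skeleton_phantom(cs[[1]], arm_length_um = cs[[2]])
    ns <- skeletonize_and_measure(ph$mask)
    expect_equal(nrow(ns$junctions), ph$truth$junctions,
                 info = cs[[1]])
    expect_lt(abs(ns$total_length_um - ph$truth$total_length_um) /
                ph$truth$total_length_um, 0.02)
  }
  # a bar has one segment bounded by two endpoints; a Y has three arms
  bar <- skeletonize_and_measure(generate_skeleton_phantom("bar", 100)$mask)
  expect_equal(nrow(bar$segments), 1)
  expect_equal(nrow(bar$endpoints), 2)
  y <- skeletonize_and_measure(generate_skeleton_phantom("Y", 50)$mask)
  expect_equal(nrow(y$segments), 3)
  x <- skeletonize_and_measure(generate_skeleton_phantom("cross", 60)$mask)
  expect_equal(nrow(x$segments), 4)
})

test_that("metrics are additive over disjoint structures", {
  y <- generate_skeleton_phantom("Y", 50)$mask$pixels
  b <- generate_skeleton_phantom("bar", 80)$mask$pixels
  H <- max(nrow(y), nrow(b))
  W <- ncol(y) + ncol(b) + 20L
  un <- matrix(FALSE, H, W)
  un[seq_len(nrow(y)), seq_len(ncol(y))] <- y
  un[seq_len(nrow(b)), ncol(y) + 20L + seq_len(ncol(b))] <- b
  m_y <- skeletonize_and_measure(binary_mask(y, 1))
  m_b <- skeletonize_and_measure(binary_mask(b, 1))
  m_u <- skeletonize_and_measure(binary_mask(un, 1))
  expect_equal(nrow(m_u$junctions), nrow(m_y$junctions) + nrow(m_b$junctions))
  expect_equal(m_u$total_length_um,
               m_y$total_length_um + m_b$total_length_um, tolerance = 1e-9)
})

test_that("doubling the pixel size doubles lengths, not junction counts", {
  ph <- generate_skeleton_phantom("Y", 50)
  m1 <- skeletonize_and_measure(ph$mask)
  m2 <- skeletonize_and_measure(binary_mask(ph$mask$pixels, 2))
  expect_equal(nrow(m2$junctions), nrow(m1$junctions))
  expect_equal(m2$total_length_um, 2 * m1$total_length_um)
})

test_that("segment lengths bound the Euclidean node distance from below", {
  for (kind in c("Y", "cross", "lattice")) {
    ns <- skeletonize_and_measure(
      generate_skeleton_phantom(kind, 60)$mask)
    eu <- sqrt((ns$segments$end1_row - ns$segments$end2_row)^2 +
                 (ns$segments$end1_col - ns$segments$end2_col)^2)
    expect_true(all(ns$segments$length_um >= eu * ns$pixel_size_um - 1e-9))
  }
})

test_that("network binarization recovers a bright synthetic network", {
  sc <- generate_scene(scene_spec(seed = 303, n_intravascular = 0,
                                  n_extravascular = 0, dropout_fraction = 0))
  m <- binarize_network(sc$channels$gfp)
  expect_gte(mask_iou(m, sc$truth$vessel_mask), 0.9)
  # inverted-contrast input with the polarity flag
  inv <- calibrated_image(max(sc$channels$gfp$pixels) - sc$channels$gfp$pixels,
                          "gfp", 1)
  m_inv <- binarize_network(inv, polarity = "dark")
  expect_gte(mask_iou(m_inv, sc$truth$vessel_mask), 0.9)
  expect_warning(m0 <- binarize_network(calibrated_image(matrix(3, 20, 20),
                                                         "gfp", 1)),
                 "constant")
  expect_false(any(m0$pixels))
})

test_that("per-FOV summaries report junctions and total tubule length", {
  empty <- skeletonize_and_measure(binary_mask(matrix(FALSE, 30, 30), 1))
  s0 <- network_summary(empty, "fov0")
  expect_equal(s0$junctions_per_fov, 0)
  expect_equal(s0$total_tubule_length_um_per_fov, 0)
  # two disjoint straight 100 um segments: (0 junctions, ~200 um)
  m <- matrix(FALSE, 40, 120)
  m[10, 11:110] <- TRUE
  m[30, 11:110] <- TRUE
  s2 <- network_summary(skeletonize_and_measure(binary_mask(m, 1)), "fov2")
  expect_equal(s2$junctions_per_fov, 0)
  expect_equal(s2$total_tubule_length_um_per_fov, 198, tolerance = 0.02)
  # Y phantom with 50 um arms: one junction, ~150 um
  y <- network_summary(skeletonize_and_measure(
    generate_skeleton_phantom("Y", 50)$mask), "fovY")
  expect_equal(y$junctions_per_fov, 1)
  expect_equal(y$total_tubule_length_um_per_fov, 150, tolerance = 0.03)
})

test_that("spur pruning drops short terminal segments only", {
  # Y with one much shorter arm rendered manually: vertical + two diagonals
  m <- matrix(FALSE, 80, 80)
  m[40, 10:70] <- TRUE     # horizontal bar
  m[30:39, 40] <- TRUE     # short vertical spur (10 px)
  ns <- skeletonize_and_measure(binary_mask(m, 1), min_spur_um = 0)
  pruned <- skeletonize_and_measure(binary_mask(m, 1), min_spur_um = 15)
  expect_equal(nrow(pruned$segments), nrow(ns$segments) - 1)
  expect_lt(pruned$total_length_um, ns$total_length_um)
})
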