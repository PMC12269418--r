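test_that("IsoData threshold is the intermeans fixed point", {
  img <- calibrated_image(matrix(rep(c(50, 200), each = 128), 16, 16), "gfp", 1)
  expect_equal(isodata_threshold(img), 125)
  m <- default_threshold(img)
  expect_equal(sum(m$pixels), 128)
  expect_true(all(img$pixels[m$pixels] == 200))
})

test_that("IsoData iterative solution matches brute-force fixed-point search", {
  # for integer data the intermeans map is piecewise constant; brute force
  # enumerates the brackets [k, k+1) containing a fixed point and the
  # iterative solution must be the intermeans value of one of them
  set.seed(21)
  for (i in 1:20) {
    v <- c(round(rnorm(300, 60, 12)), round(rnorm(120, 190, 20)))
    v <- pmax(v, 0)
    intermeans <- function(t) {
      lo <- v[v <= t]; hi <- v[v > t]
      if (!length(lo) || !length(hi)) return(NA_real_)
      (mean(lo) + mean(hi)) / 2
    }
    brackets <- Filter(function(k) {
      m <- intermeans(k)
      !is.na(m) && m >= k && m < k + 1
    }, seq(min(v), max(v)))
    t_iter <- isodata_threshold(matrix(v, 20))
    expect_true(floor(t_iter) %in% brackets)
    expect_equal(t_iter, intermeans(floor(t_iter)), tolerance = 1e-6)
    # foreground count equals brute-force count at the same threshold
    img <- calibrated_image(matrix(v, 20), "gfp", 1)
    expect_equal(sum(default_threshold(img)$pixels), sum(v > t_iter))
  }
})

test_that("constant images yield an all-background mask with a warning", {
  img <- calibrated_image(matrix(7, 10, 10), "gfp", 1)
  expect_warning(m <- default_threshold(img), "constant")
  expect_false(any(m$pixels))
})

test_that("classifier separates a two-class fixture and is deterministic", {
  fix <- separable_fixture(seed = 5)
  st <- compute_feature_stack(fix$img, tiny_features())
  lab <- scribbles_for_fixture(fix, n = 100, seed = 2)
  cl <- train_pixel_classifier(st, lab, n_trees = 50, random_seed = 7)
  expect_equal(cl$training_summary$n_vessel, 100)
  expect_equal(cl$training_summary$oob_accuracy, 1.0)
  pred <- predict_mask(cl, st)
  expect_gte(mask_iou(pred, fix$truth), 0.95)
  # determinism: retrain with the same seed, identical prediction
  cl2 <- train_pixel_classifier(st, lab, n_trees = 50, random_seed = 7)
  expect_identical(predict_mask(cl2, st)$pixels, pred$pixels)
  expect_identical(predict_mask(cl, st)$pixels, pred$pixels)
})

test_that("an all-background image predicts a near-empty mask", {
  fix <- separable_fixture(seed = 6)
  st <- compute_feature_stack(fix$img, tiny_features())
  cl <- train_pixel_classifier(st, scribbles_for_fixture(fix), n_trees = 50,
                               random_seed = 1)
  set.seed(8)
  bg <- calibrated_image(matrix(pmax(rnorm(64^2, 50, 5), 0), 64, 64),
                         "phase", 1)
  pred <- predict_mask(cl, compute_feature_stack(bg, tiny_features()))
  expect_lt(mean(pred$pixels), 0.01)
})

test_that("single-class labels and mismatched stacks are rejected", {
  fix <- separable_fixture(seed = 7)
  st <- compute_feature_stack(fix$img, tiny_features())
  coords <- which(fix$truth$pixels, arr.ind = TRUE)[1:20, ]
  expect_error(train_pixel_classifier(st, scribble_labels(
    coords, rep("vessel", 20))), "both classes")
  cl <- train_pixel_classifier(st, scribbles_for_fixture(fix), n_trees = 20,
                               random_seed = 1)
  other <- compute_feature_stack(fix$img, feature_config(
    sigma_min = 1, sigma_max = 4, families = "gaussian_blur"))
  expect_error(predict_mask(cl, other), "match")
})

test_that("prediction is invariant to feature-plane order", {
  fix <- separable_fixture(seed = 9)
  st <- compute_feature_stack(fix$img, tiny_features())
  cl <- train_pixel_classifier(st, scribbles_for_fixture(fix), n_trees = 30,
                               random_seed = 3)
  pred <- predict_mask(cl, st)
  perm <- rev(seq_along(st$names))
  shuffled <- st
  shuffled$features <- st$features[, , perm]
  shuffled$names <- st$names[perm]
  expect_identical(predict_mask(cl, shuffled)$pixels, pred$pixels)
})

test_that("morphological cleanup removes speckle and respects set bounds", {
  m <- matrix(FALSE, 20, 20)
  m[5, 5] <- TRUE               # isolated speckle
  m[10:16, 8:14] <- TRUE        # solid block
  mask <- binary_mask(m, 1)
  out <- morph_clean(mask, 1, 1)
  expect_false(out$pixels[5, 5])
  # opening: anti-extensive (within the input) but keeps the block interior
  expect_true(all(out$pixels[11:15, 9:13]))
  expect_true(all(!out$pixels[!m]))
  # block area is preserved up to a 1-px boundary band
  expect_gte(sum(out$pixels), sum(m) - 1 - (2 * 7 + 2 * 7))
  expect_identical(morph_clean(mask, 0, 0)$pixels, mask$pixels)
})

test_that("classifier persistence round-trips and checks its config", {
  fix <- separable_fixture(seed = 12)
  st <- compute_feature_stack(fix$img, tiny_features())
  cl <- train_pixel_classifier(st, scribbles_for_fixture(fix), n_trees = 20,
                               random_seed = 4)
  path <- tempfile(fileext = ".rds")
  save_classifier(cl, path)
  back <- load_classifier(path, expected_config = tiny_features())
  expect_identical(predict_mask(back, st)$pixels, predict_mask(cl, st)$pixels)
  expect_error(load_classifier(path, expected_config = feature_config()),
               "configuration")
})
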