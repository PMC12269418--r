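# Vessel segmentation: GFP pre-thresholding, random-forest pixel
# classification over the feature bank, and morphological cleanup.
#
# The classifier follows the fast-random-forest setting used for MVN
# segmentation: 200 trees; the historical batch size of 100 is recorded as
# provenance only (a prediction-batching detail, not a model parameter).

# Histogram of intensities over integer-ish bins. For integer-valued images
# each bin is one gray level (ImageJ-like behavior); otherwise 256 bins span
# the range.
intensity_histogram <- function(px) {
  v <- as.vector(px)
  if (all(v == round(v)) && diff(range(v)) <= 65535) {
    lo <- min(v)
    levels <- seq(lo, max(v))
    counts <- tabulate(v - lo + 1L, nbins = length(levels))
  } else {
    breaks <- seq(min(v), max(v), length.out = 257L)
    idx <- pmin(findInterval(v, breaks), 256L)
    levels <- (breaks[-257L] + breaks[-1L]) / 2
    counts <- tabulate(idx, nbins = 256L)
  }
  list(levels = levels, counts = counts)
}

#' IsoData ("default") intensity threshold
#'
#' Iterative intermeans algorithm: starting from the global mean, the
#' threshold is updated to the average of the means of the two classes it
#' induces, until it is stable. This is the classic "default" automatic
#' threshold applied to the GFP channel to pre-segment the endothelial cells.
#'
#' @param img `calibrated_image`, `binary_mask` or matrix.
#' @return The converged threshold intensity (foreground is strictly above),
#'   or `NA` with a warning for a constant image.
#' @export
isodata_threshold <- function(img) {
  px <- as_pixels(img)
  v <- as.vector(px)
  if (diff(range(v)) == 0) {
    warning("constant image: no threshold exists, returning NA")
    return(NA_real_)
  }
  h <- intensity_histogram(px)
  lv <- h$levels; ct <- h$counts
  t_cur <- sum(lv * ct) / sum(ct)
  for (iter in 1:1000) {
    below <- lv <= t_cur
    m1 <- sum(lv[below] * ct[below]) / max(sum(ct[below]), 1)
    m2 <- sum(lv[!below] * ct[!below]) / max(sum(ct[!below]), 1)
    if (sum(ct[below]) == 0) m1 <- m2
    if (sum(ct[!below]) == 0) m2 <- m1
    t_new <- (m1 + m2) / 2
    if (abs(t_new - t_cur) < 1e-9) break
    t_cur <- t_new
  }
  t_cur
}

#' Threshold an image with the IsoData criterion
#'
#' @param img `calibrated_image`.
#' @return A `binary_mask` with pixels strictly above the converged
#'   threshold as foreground; an all-background mask (with a warning) for a
#'   constant image.
#' @export
default_threshold <- function(img) {
  stopifnot(inherits(img, "calibrated_image"))
  thr <- isodata_threshold(img)
  if (is.na(thr)) {
    return(binary_mask(matrix(FALSE, nrow(img$pixels), ncol(img$pixels)),
                       img$pixel_size_um, provenance = "default_threshold:constant"))
  }
  binary_mask(img$pixels > thr, img$pixel_size_um,
              provenance = sprintf("default_threshold:%.6g", thr))
}

#' Scribble labels for classifier training
#'
#' Sparse user-provided class labels at pixel coordinates, with vessels as
#' one class and spheroids plus background as the other.
#'
#' @param coordinates Two-column matrix/data.frame of (row, col), 1-based.
#' @param classes Character vector, one of `"vessel"`/`"background"` per
#'   coordinate.
#' @param image_id Identifier linking the labels to their source image.
#' @return An object of class `scribble_labels`.
#' @export
scribble_labels <- function(coordinates, classes, image_id = "") {
  coordinates <- as.matrix(coordinates)
  abort_if(ncol(coordinates) != 2L, "coordinates must have 2 columns (row, col)")
  abort_if(nrow(coordinates) != length(classes),
           "coordinates and classes must be parallel")
  abort_if(!all(classes %in% c("vessel", "background")),
           "classes must be 'vessel' or 'background'")
  structure(list(coordinates = coordinates, classes = as.character(classes),
                 image_id = image_id),
            class = "scribble_labels")
}

#' Read scribble labels from a CSV file
#'
#' Expected columns: `row`, `col`, `class`.
#'
#' @param path CSV path.
#' @param image_id Identifier for the source image.
#' @return A `scribble_labels` object.
#' @export
read_scribbles_csv <- function(path, image_id = path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(!all(c("row", "col", "class") %in% names(df)),
           "scribble CSV needs columns: row, col, class")
  scribble_labels(cbind(df$row, df$col), df$class, image_id)
}

#' Train the random-forest pixel classifier
#'
#' Fits a random forest (default 200 trees) on the per-pixel feature vectors
#' at the scribble coordinates. Identical inputs and seed give identical
#' model decisions.
#'
#' @param stack A [compute_feature_stack()] result covering the label
#'   coordinates, or a list of stacks (one per training image).
#' @param labels A [scribble_labels()] object containing both classes, or a
#'   parallel list of them when `stack` is a list.
#' @param n_trees Number of trees (default 200).
#' @param random_seed Integer seed controlling forest construction.
#' @return An object of class `pixel_classifier` with the fitted forest,
#'   the feature configuration, and a training summary (per-class counts and
#'   out-of-bag accuracy).
#' @export
train_pixel_classifier <- function(stack, labels, n_trees = 200L,
                                   random_seed = 1L) {
  if (inherits(stack, "feature_stack")) stack <- list(stack)
  if (inherits(labels, "scribble_labels")) labels <- list(labels)
  abort_if(length(stack) != length(labels),
           "need one scribble set per feature stack")
  abort_if(length(stack) == 0L, "no training data supplied")
  for (s in stack) {
    stopifnot(inherits(s, "feature_stack"))
    abort_if(!identical(s$names, stack[[1]]$names),
             "all training stacks must share the same feature bank")
  }
  abort_if(n_trees < 1, "n_trees must be >= 1")
  classes <- unlist(lapply(labels, function(l) l$classes))
  abort_if(length(unique(classes)) < 2L,
           "training labels must contain both classes")
  x <- do.call(rbind, lapply(seq_along(stack), function(i) {
    s <- stack[[i]]; l <- labels[[i]]
    stopifnot(inherits(l, "scribble_labels"))
    d <- dim(s$features)
    co <- l$coordinates
    abort_if(any(co[, 1] < 1 | co[, 1] > d[1] | co[, 2] < 1 | co[, 2] > d[2]),
             "scribble coordinates outside the feature stack")
    stack_matrix(s, (co[, 2] - 1L) * d[1] + co[, 1])
  }))
  df <- as.data.frame(x)
  names(df) <- sprintf("f%03d", seq_len(ncol(df)))
  df$.class <- factor(classes, levels = c("background", "vessel"))
  stack1 <- stack[[1]]
  labels_all <- classes
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = as.integer(n_trees), probability = TRUE,
    seed = as.integer(random_seed), num.threads = 1L,
    respect.unordered.factors = "order"
  )
  oob_pred <- fit$predictions[, "vessel"] > 0.5
  oob_acc <- mean(oob_pred == (labels_all == "vessel"), na.rm = TRUE)
  structure(
    list(n_trees = as.integer(n_trees), batch_size = 100L,
         feature_config = stack1$config, feature_names = stack1$names,
         random_seed = as.integer(random_seed), fitted_model = fit,
         training_summary = list(
           n_vessel = sum(labels_all == "vessel"),
           n_background = sum(labels_all == "background"),
           oob_accuracy = oob_acc)),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(paste0("<pixel_classifier> %d trees, seed %d, %d features\n",
                     "  training: %d vessel / %d background px, OOB accuracy %.3f\n"),
              x$n_trees, x$random_seed, length(x$feature_names),
              x$training_summary$n_vessel, x$training_summary$n_background,
              x$training_summary$oob_accuracy))
  invisible(x)
}

#' Predict a binary vessel mask
#'
#' Applies the trained forest to every pixel of a feature stack. The stack's
#' feature planes are matched to the classifier by name, so plane order is
#' irrelevant; a name mismatch is an error. Pixels with vessel probability
#' strictly above 0.5 are vessel (ties go to background: conservative vessel
#' calls reduce false intravasation events).
#'
#' @param classifier A [train_pixel_classifier()] result.
#' @param stack A feature stack computed with a matching configuration.
#' @param pixel_size_um Calibration to attach to the mask.
#' @return A `binary_mask` of the vessel class.
#' @export
predict_mask <- function(classifier, stack, pixel_size_um = 1) {
  stopifnot(inherits(classifier, "pixel_classifier"),
            inherits(stack, "feature_stack"))
  abort_if(!setequal(stack$names, classifier$feature_names),
           "feature stack does not match the classifier's feature bank")
  x <- stack_matrix(stack)
  x <- x[, match(classifier$feature_names, colnames(x)), drop = FALSE]
  df <- as.data.frame(x)
  names(df) <- sprintf("f%03d", seq_len(ncol(df)))
  pr <- stats::predict(classifier$fitted_model, data = df,
                       num.threads = 1L)$predictions
  d <- dim(stack$features)
  vessel <- matrix(pr[, "vessel"] > 0.5, d[1], d[2])
  binary_mask(vessel, pixel_size_um, provenance = "predict_mask")
}

cross_kernel <- function() {
  matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
}

#' Morphological cleanup of a binary mask
#'
#' Applies `n_erosions` erosions followed by `n_dilations` dilations with a
#' fixed 3x3 cross structuring element. With (1, 1) this is a morphological
#' opening that removes isolated single-pixel speckle.
#'
#' @param mask A `binary_mask`.
#' @param n_erosions,n_dilations Non-negative iteration counts.
#' @return A cleaned `binary_mask`.
#' @export
morph_clean <- function(mask, n_erosions = 1L, n_dilations = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  abort_if(n_erosions < 0 || n_dilations < 0, "iteration counts must be >= 0")
  m <- mask$pixels * 1
  k <- cross_kernel()
  if (n_erosions > 0) for (i in seq_len(n_erosions)) m <- EBImage::erode(m, k)
  if (n_dilations > 0) for (i in seq_len(n_dilations)) m <- EBImage::dilate(m, k)
  binary_mask(as.matrix(m) > 0, mask$pixel_size_um,
              provenance = sprintf("%s|morph_clean(%d,%d)", mask$provenance,
                                   n_erosions, n_dilations))
}

#' Save a trained pixel classifier
#'
#' Persists the fitted forest together with its feature configuration, seed
#' and training summary so that a prediction run can verify compatibility.
#' The file is an RDS archive.
#'
#' @param classifier A `pixel_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' Load a trained pixel classifier
#'
#' @param path Path written by [save_classifier()].
#' @param expected_config Optional [feature_config()]; loading fails if the
#'   stored configuration differs.
#' @return A `pixel_classifier`.
#' @export
load_classifier <- function(path, expected_config = NULL) {
  cl <- readRDS(path)
  abort_if(!inherits(cl, "pixel_classifier"),
           sprintf("%s is not a pixel classifier file", path))
  if (!is.null(expected_config)) {
    abort_if(!identical(unclass(cl$feature_config), unclass(expected_config)),
             "stored classifier feature configuration does not match")
  }
  cl
}
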