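# Weka-style per-pixel feature bank for vessel classification.
#
# The bank mirrors the Trainable-Weka-Segmentation setting used for MVN
# segmentation: Gaussian blur, Sobel, Hessian eigenvalues, difference of
# Gaussians and membrane projections, computed on a geometric ladder of
# scales between sigma_min and sigma_max. All convolutions use reflect
# padding so that features are translation-equivariant away from borders.

FEATURE_FAMILIES <- c("gaussian_blur", "sobel", "hessian",
                      "difference_of_gaussians", "membrane_projections")

#' Configuration of the pixel feature bank
#'
#' Defaults follow the segmentation settings used for the intravasation
#' analysis: membrane thickness 1 px, membrane patch size 19 px, minimum
#' sigma 1.0, maximum sigma 16.0, and the five feature families Gaussian
#' blur, Sobel, Hessian, difference of Gaussians and membrane projections.
#' Membrane kernels are rotated in 30 steps of 6 degrees.
#'
#' @param membrane_thickness Line width of the membrane kernel (px).
#' @param membrane_patch_size Membrane kernel side (px); odd, >= 3.
#' @param sigma_min,sigma_max Smoothing-scale bounds (px); the bank uses the
#'   geometric ladder `sigma_min * 2^k` up to and including `sigma_max`.
#' @param families Non-empty subset of
#'   `c("gaussian_blur", "sobel", "hessian", "difference_of_gaussians",
#'   "membrane_projections")`.
#' @param n_membrane_rotations Number of rotated membrane kernels.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(membrane_thickness = 1L,
                           membrane_patch_size = 19L,
                           sigma_min = 1.0, sigma_max = 16.0,
                           families = FEATURE_FAMILIES,
                           n_membrane_rotations = 30L) {
  abort_if(!is_scalar_number(sigma_min) || !is_scalar_number(sigma_max) ||
             sigma_min <= 0 || sigma_min > sigma_max,
           "need 0 < sigma_min <= sigma_max")
  abort_if(membrane_patch_size < 3 || membrane_patch_size %% 2 == 0,
           "membrane_patch_size must be odd and >= 3")
  abort_if(membrane_thickness < 1, "membrane_thickness must be >= 1")
  families <- match.arg(families, FEATURE_FAMILIES, several.ok = TRUE)
  abort_if(length(families) == 0L, "families must be non-empty")
  abort_if(n_membrane_rotations < 1, "n_membrane_rotations must be >= 1")
  structure(
    list(membrane_thickness = as.integer(membrane_thickness),
         membrane_patch_size = as.integer(membrane_patch_size),
         sigma_min = sigma_min, sigma_max = sigma_max,
         families = families,
         n_membrane_rotations = as.integer(n_membrane_rotations)),
    class = "feature_config"
  )
}

#' Geometric scale ladder of a feature configuration
#'
#' @param config A [feature_config()].
#' @return Increasing numeric vector `sigma_min * 2^k`, capped at and
#'   including `sigma_max` when it lies on the ladder.
#' @export
scale_set <- function(config) {
  stopifnot(inherits(config, "feature_config"))
  s <- config$sigma_min
  out <- numeric(0)
  while (s <= config$sigma_max * (1 + 1e-12)) {
    out <- c(out, s)
    s <- s * 2
  }
  out
}

as_pixels <- function(img) {
  if (inherits(img, "calibrated_image")) img$pixels
  else if (inherits(img, "binary_mask")) img$pixels * 1.0
  else if (is.matrix(img)) img
  else stop("expected a calibrated_image, binary_mask or matrix", call. = FALSE)
}

#' Difference of Gaussians feature plane
#'
#' Convention: blur at the smaller sigma minus blur at the larger sigma,
#' regardless of argument order, so band-pass responses have a fixed sign.
#'
#' @param img `calibrated_image` or matrix.
#' @param sigma_a,sigma_b Positive Gaussian scales.
#' @return Matrix of the same shape.
#' @export
difference_of_gaussians <- function(img, sigma_a, sigma_b) {
  abort_if(!is_scalar_number(sigma_a) || sigma_a <= 0 ||
             !is_scalar_number(sigma_b) || sigma_b <= 0,
           "sigmas must be > 0")
  m <- as_pixels(img)
  lo <- min(sigma_a, sigma_b); hi <- max(sigma_a, sigma_b)
  if (lo == hi) return(matrix(0, nrow(m), ncol(m)))
  gauss_blur(m, lo) - gauss_blur(m, hi)
}

sobel_kernels <- function() {
  gx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  list(gx = gx, gy = t(gx))
}

#' Sobel gradient-magnitude feature plane
#'
#' @param img `calibrated_image` or matrix.
#' @param sigma Gaussian pre-smoothing scale (> 0).
#' @return Matrix of gradient magnitudes.
#' @export
sobel_magnitude <- function(img, sigma = 1) {
  abort_if(!is_scalar_number(sigma) || sigma <= 0, "sigma must be > 0")
  m <- gauss_blur(as_pixels(img), sigma)
  k <- sobel_kernels()
  gx <- conv_reflect(m, k$gx)
  gy <- conv_reflect(m, k$gy)
  sqrt(gx^2 + gy^2)
}

#' Hessian eigenvalue feature planes
#'
#' Per-pixel eigenvalues of the Hessian of the Gaussian-smoothed image,
#' computed with central finite differences. Ridge-like vessel structures
#' produce a strongly negative smallest eigenvalue along bright ridges.
#'
#' @param img `calibrated_image` or matrix.
#' @param sigma Gaussian smoothing scale (> 0).
#' @return List with matrices `largest` and `smallest` (ordered per pixel).
#' @export
hessian_eigenimages <- function(img, sigma = 1) {
  abort_if(!is_scalar_number(sigma) || sigma <= 0, "sigma must be > 0")
  m <- gauss_blur(as_pixels(img), sigma)
  dxx <- matrix(c(1, -2, 1), 1, 3)
  dyy <- t(dxx)
  dx <- matrix(c(-0.5, 0, 0.5), 1, 3)
  dy <- t(dx)
  # rows are y (first index), columns are x; mixed derivative via two passes
  hxx <- conv_reflect(m, dxx)
  hyy <- conv_reflect(m, dyy)
  hxy <- conv_reflect(conv_reflect(m, dx), dy)
  tr <- hxx + hyy
  disc <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
  list(largest = (tr + disc) / 2, smallest = (tr - disc) / 2)
}

# One rotated line kernel: patch_size x patch_size, a central line of width
# `thickness` at angle `theta`, normalized to unit mass.
membrane_kernel <- function(patch_size, thickness, theta) {
  r <- (patch_size - 1) / 2
  g <- expand.grid(y = -r:r, x = -r:r)
  # signed distance from the line through the origin at angle theta
  d <- abs(-sin(theta) * g$x + cos(theta) * g$y)
  on <- d <= (thickness / 2 + 1e-9)
  k <- matrix(0, patch_size, patch_size)
  k[cbind(g$y + r + 1, g$x + r + 1)] <- as.numeric(on)
  k / sum(k)
}

#' Membrane-projection feature planes
#'
#' Convolves the image with `n_membrane_rotations` rotated line kernels
#' (`membrane_patch_size` square, line width `membrane_thickness`) and
#' reduces across rotations by sum, mean, standard deviation, median, max
#' and min — six planes in that fixed order.
#'
#' @param img `calibrated_image` or matrix.
#' @param config A [feature_config()].
#' @return List of six matrices named
#'   `sum`, `mean`, `sd`, `median`, `max`, `min`.
#' @export
membrane_projections <- function(img, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  m <- as_pixels(img)
  n <- config$n_membrane_rotations
  thetas <- (seq_len(n) - 1) * pi / n
  H <- nrow(m); W <- ncol(m)
  resp <- matrix(0, H * W, n)
  for (i in seq_len(n)) {
    k <- membrane_kernel(config$membrane_patch_size,
                         config$membrane_thickness, thetas[i])
    resp[, i] <- as.vector(conv_reflect(m, k))
  }
  shape <- function(v) matrix(v, H, W)
  s1 <- matrixStats::rowSums2(resp)
  mu <- s1 / n
  sdp <- sqrt(pmax(matrixStats::rowSums2(resp^2) / n - mu^2, 0))
  list(sum = shape(s1), mean = shape(mu), sd = shape(sdp),
       median = shape(matrixStats::rowMedians(resp)),
       max = shape(matrixStats::rowMaxs(resp)),
       min = shape(matrixStats::rowMins(resp)))
}

#' Compute the full per-pixel feature stack
#'
#' Concatenates, per channel, the raw intensity plane plus every enabled
#' feature family at every scale of [scale_set()]. Difference-of-Gaussians
#' planes are formed for all ordered scale pairs `sigma_i < sigma_j`.
#'
#' @param channels A `calibrated_image`, `binary_mask`, or list of them; all
#'   must share the same shape.
#' @param config A [feature_config()].
#' @return An object of class `feature_stack`: list with `features`
#'   (H x W x n array), `names` (unique plane labels) and `source_channels`.
#' @export
compute_feature_stack <- function(channels, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  if (!is.list(channels) || inherits(channels, "calibrated_image") ||
      inherits(channels, "binary_mask")) {
    channels <- list(channels)
  }
  abort_if(length(channels) == 0L, "at least one channel required")
  mats <- lapply(channels, as_pixels)
  dims <- vapply(mats, dim, integer(2))
  abort_if(any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]),
           "all channels must share the same shape")
  roles <- vapply(seq_along(channels), function(i) {
    ch <- channels[[i]]
    if (inherits(ch, "calibrated_image")) ch$channel_role
    else sprintf("channel%d", i)
  }, character(1))
  if (anyDuplicated(roles)) {
    roles <- make.unique(roles, sep = "_")
  }
  sigmas <- scale_set(config)
  planes <- list(); labels <- character(0)
  add <- function(p, lab) {
    planes[[length(planes) + 1L]] <<- p
    labels <<- c(labels, lab)
  }
  for (ci in seq_along(mats)) {
    m <- mats[[ci]]; role <- roles[ci]
    add(m, sprintf("%s|raw", role))
    if ("gaussian_blur" %in% config$families) {
      for (s in sigmas) add(gauss_blur(m, s),
                            sprintf("%s|gaussian_blur|s=%g", role, s))
    }
    if ("sobel" %in% config$families) {
      for (s in sigmas) add(sobel_magnitude(m, s),
                            sprintf("%s|sobel|s=%g", role, s))
    }
    if ("hessian" %in% config$families) {
      for (s in sigmas) {
        h <- hessian_eigenimages(m, s)
        add(h$largest, sprintf("%s|hessian_max|s=%g", role, s))
        add(h$smallest, sprintf("%s|hessian_min|s=%g", role, s))
      }
    }
    if ("difference_of_gaussians" %in% config$families && length(sigmas) > 1) {
      for (i in seq_len(length(sigmas) - 1)) {
        for (j in seq(i + 1, length(sigmas))) {
          add(difference_of_gaussians(m, sigmas[i], sigmas[j]),
              sprintf("%s|dog|s=%g-%g", role, sigmas[i], sigmas[j]))
        }
      }
    }
    if ("membrane_projections" %in% config$families) {
      mp <- membrane_projections(m, config)
      for (nm in names(mp)) add(mp[[nm]], sprintf("%s|membrane_%s", role, nm))
    }
  }
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  feat <- array(0, c(H, W, length(planes)))
  for (i in seq_along(planes)) feat[, , i] <- planes[[i]]
  abort_if(anyDuplicated(labels) > 0, "internal: duplicate feature names")
  structure(
    list(features = feat, names = labels, source_channels = roles,
         config = config),
    class = "feature_stack"
  )
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %dx%d px, %d planes, channels: %s\n",
              dim(x$features)[1], dim(x$features)[2], length(x$names),
              paste(x$source_channels, collapse = ", ")))
  invisible(x)
}

# Flatten a feature stack into an (n_pixels x n_features) matrix.
stack_matrix <- function(stack, idx = NULL) {
  d <- dim(stack$features)
  m <- matrix(stack$features, d[1] * d[2], d[3])
  colnames(m) <- stack$names
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}
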