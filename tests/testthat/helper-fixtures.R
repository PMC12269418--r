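# Shared fixtures built in code: rasterized shapes, small feature
# configurations, and a fast scene spec for pipeline tests.

raster_disk <- function(r, pad = 3L) {
  n <- 2L * r + 2L * pad
  cc <- (n + 1) / 2
  g <- expand.grid(seq_len(n), seq_len(n))
  matrix((g[, 1] - cc)^2 + (g[, 2] - cc)^2 <= r^2, n, n)
}

raster_ellipse <- function(a, b, theta = 0, pad = 10L) {
  n <- 2L * a + 2L * pad
  cc <- (n + 1) / 2
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  x <- g$x - cc; y <- g$y - cc
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  matrix(xr^2 / a^2 + yr^2 / b^2 <= 1, n, n)
}

mask_iou <- function(a, b) {
  pa <- if (inherits(a, "binary_mask")) a$pixels else a
  pb <- if (inherits(b, "binary_mask")) b$pixels else b
  sum(pa & pb) / sum(pa | pb)
}

# Minimal feature bank: fast enough for per-test classifier training.
tiny_features <- function() {
  feature_config(sigma_min = 1, sigma_max = 2,
                 families = c("gaussian_blur", "sobel"))
}

# Feature bank used by the simulation-study pipeline tests: small scale
# ladder, no membrane projections.
light_features <- function() {
  feature_config(sigma_min = 1, sigma_max = 8,
                 families = c("gaussian_blur", "sobel",
                              "difference_of_gaussians"))
}

# Two-class fixture: bright "vessel" band on a dark background, with mild
# noise; separable on raw intensity alone.
separable_fixture <- function(seed = 1, size = 64L) {
  set.seed(seed)
  truth <- matrix(FALSE, size, size)
  truth[, (size %/% 3):(2L * size %/% 3)] <- TRUE
  px <- matrix(stats::rnorm(size^2, 50, 5), size, size)
  px[truth] <- stats::rnorm(sum(truth), 200, 5)
  img <- calibrated_image(pmax(px, 0), "phase", 1)
  list(img = img, truth = binary_mask(truth, 1))
}

scribbles_for_fixture <- function(fix, n = 100L, seed = 2) {
  scribbles_from_mask(fix$truth, n_per_class = n, seed = seed)
}
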