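test_that("scale ladder is the powers-of-two set between the sigma bounds", {
  expect_equal(scale_set(feature_config(sigma_min = 1, sigma_max = 16)),
               c(1, 2, 4, 8, 16))
  expect_equal(scale_set(feature_config(sigma_min = 2, sigma_max = 2)), 2)
  expect_error(feature_config(sigma_min = 4, sigma_max = 1), "sigma")
})

test_that("difference of Gaussians follows the min-minus-max convention", {
  set.seed(10)
  img <- matrix(runif(48 * 48, 0, 255), 48, 48)
  expect_equal(difference_of_gaussians(img, 2, 2),
               matrix(0, 48, 48))
  flat <- difference_of_gaussians(matrix(7, 48, 48), 1, 4)
  expect_lt(max(abs(flat)), 1e-9)
  # orientation is fixed regardless of argument order
  expect_equal(difference_of_gaussians(img, 1, 4),
               difference_of_gaussians(img, 4, 1))
  expect_error(difference_of_gaussians(img, -1, 2), "sigma")
})

test_that("DoG of a unit impulse equals the analytic kernel difference", {
  n <- 65L
  img <- matrix(0, n, n); img[33, 33] <- 1
  out <- difference_of_gaussians(img, 1.5, 3)
  g <- function(s) {
    d <- outer((1:n) - 33, (1:n) - 33, function(a, b) a^2 + b^2)
    k <- exp(-d / (2 * s^2)); k / sum(k)
  }
  expect_lt(max(abs(out - (g(1.5) - g(3)))), 1e-6)
})

test_that("Hessian eigenvalues match analytic second derivatives", {
  flat <- hessian_eigenimages(matrix(5, 40, 40), 2)
  expect_lt(max(abs(flat$largest)), 1e-8)
  expect_lt(max(abs(flat$smallest)), 1e-8)
  # f(x, y) = x^2 has d2f/dx2 = 2, all other second derivatives 0
  n <- 61L
  ramp <- outer(rep(1, n), as.numeric(1:n), function(y, x) (x - 31)^2)
  h <- hessian_eigenimages(ramp, 1.5)
  interior <- 20:42
  expect_lt(max(abs(h$largest[interior, interior] - 2)), 1e-6)
  expect_lt(max(abs(h$smallest[interior, interior])), 1e-6)
  # bright horizontal ridge: strongly negative curvature across the ridge
  ridge <- matrix(0, n, n); ridge[31, ] <- 100
  hr <- hessian_eigenimages(ridge, 2)
  expect_lt(max(hr$smallest[31, 20:42]), -1)
  expect_lt(mean(hr$smallest[31, 20:42]), mean(hr$smallest[10, 20:42]))
})

test_that("membrane kernels have the configured geometry", {
  k <- mvnquant:::membrane_kernel(19, 1, 0)
  expect_identical(dim(k), c(19L, 19L))
  expect_equal(sum(k > 0), 19L)
  expect_equal(sum(k), 1)
  # thickness-1 kernels at any rotation stay a thin line
  for (th in seq(0, pi, length.out = 7)) {
    kk <- mvnquant:::membrane_kernel(19, 1, th)
    expect_lte(sum(kk > 0), 2 * 19)
    expect_equal(sum(kk), 1)
  }
})

test_that("membrane projections reduce rotations in the documented order", {
  cfg <- feature_config(n_membrane_rotations = 12)
  mp <- membrane_projections(matrix(3, 30, 30), cfg)
  expect_identical(names(mp), c("sum", "mean", "sd", "median", "max", "min"))
  expect_lt(max(abs(mp$mean - 3)), 1e-9)
  expect_lt(max(abs(mp$sd)), 1e-9)
  expect_lt(max(abs(mp$sum - 12 * 3)), 1e-8)
  # a single bright line: the max projection peaks on the line
  img <- matrix(0, 41, 41); img[21, 6:36] <- 10
  mx <- membrane_projections(img, cfg)$max
  expect_equal(which(mx == max(mx), arr.ind = TRUE)[1, 1][[1]], 21L)
  # max over rotations is at least the 0-degree response everywhere
  k0 <- mvnquant:::membrane_kernel(cfg$membrane_patch_size,
                                   cfg$membrane_thickness, 0)
  r0 <- mvnquant:::conv_reflect(img, k0)
  expect_true(all(mx - r0 > -1e-9))
})

test_that("feature stack enumerates the configured bank per channel", {
  img <- calibrated_image(matrix(runif(32 * 32), 32, 32), "phase", 1)
  cfg <- feature_config(sigma_min = 1, sigma_max = 16,
                        families = "gaussian_blur")
  st <- compute_feature_stack(img, cfg)
  expect_equal(length(st$names), 6) # raw + 5 blur scales
  img2 <- calibrated_image(matrix(runif(32 * 32), 32, 32), "gfp", 1)
  st2 <- compute_feature_stack(list(img, img2), cfg)
  expect_equal(length(st2$names), 12)
  expect_false(anyDuplicated(st2$names) > 0)
  bad <- calibrated_image(matrix(1, 16, 16), "gfp", 1)
  expect_error(compute_feature_stack(list(img, bad), cfg), "shape")
})

test_that("features are deterministic and translation-equivariant", {
  set.seed(11)
  base <- matrix(runif(80 * 80, 0, 200), 80, 80)
  cfg <- feature_config(sigma_min = 1, sigma_max = 4,
                        families = c("gaussian_blur", "sobel", "hessian",
                                     "difference_of_gaussians"))
  img <- calibrated_image(base, "phase", 1)
  s1 <- compute_feature_stack(img, cfg)
  s2 <- compute_feature_stack(img, cfg)
  expect_identical(s1$features, s2$features)
  # shift input by (dy, dx); interior of each plane must shift identically
  dy <- 3L; dx <- 5L
  shifted <- matrix(0, 80, 80)
  shifted[(1 + dy):80, (1 + dx):80] <- base[1:(80 - dy), 1:(80 - dx)]
  st_s <- compute_feature_stack(calibrated_image(shifted, "phase", 1), cfg)
  keep <- 25:55
  for (i in seq_along(s1$names)) {
    a <- s1$features[keep, keep, i]
    b <- st_s$features[keep + dy, keep + dx, i]
    expect_lt(max(abs(a - b)), 1e-8)
  }
})
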