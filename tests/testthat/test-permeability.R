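strip_mask <- function(width_px, H = 96, W = 64, ps = 1) {
  m <- matrix(FALSE, H, W)
  mid <- (H + 1) %/% 2
  m[(mid - width_px %/% 2):(mid + (width_px - 1) %/% 2), ] <- TRUE
  binary_mask(m, ps)
}

test_that("vessel diameter is recovered from strip masks", {
  expect_equal(measure_vessel_diameter(strip_mask(31)), 31, tolerance = 1)
  expect_equal(measure_vessel_diameter(strip_mask(30)), 30, tolerance = 1)
  expect_equal(measure_vessel_diameter(strip_mask(30, ps = 0.5)), 15,
               tolerance = 0.5)
  expect_error(measure_vessel_diameter(
    binary_mask(matrix(FALSE, 20, 20), 1)), "no vessel")
  two <- matrix(FALSE, 60, 40); two[10:15, ] <- TRUE; two[40:45, ] <- TRUE
  expect_error(measure_vessel_diameter(binary_mask(two, 1)), "exactly one")
})

test_that("the permeability formula matches hand arithmetic", {
  w <- permeability_window(I_i = 200, I_b = 100, I_f = 210, delta_t = 900,
                           d_um = 40)
  out <- permeability_coefficient(w)
  expect_equal(out$P_cm_per_s, (1 / 100) * (10 / 900) * (0.004 / 4))
  expect_equal(out$P_cm_per_s, 1.111e-7, tolerance = 1e-3)
  # no efflux: P = 0
  w0 <- permeability_window(200, 100, 200, 900, 40)
  expect_equal(permeability_coefficient(w0)$P_cm_per_s, 0)
  # bleaching-dominated: negative P reported with a QC flag, not clipped
  wn <- permeability_window(200, 100, 190, 900, 40)
  outn <- permeability_coefficient(wn)
  expect_lt(outn$P_cm_per_s, 0)
  expect_false(outn$qc_flags$nonnegative_ok)
  expect_error(permeability_window(100, 100, 110, 900, 40), "I_i")
  expect_error(permeability_window(200, 100, 210, 0, 40), "delta_t")
})

test_that("P is invariant to intensity scaling and linear in d and efflux", {
  base <- permeability_coefficient(
    permeability_window(200, 100, 230, 600, 30))$P_cm_per_s
  for (k in c(0.5, 2, 7)) {
    scaled <- permeability_coefficient(
      permeability_window(200 * k, 100 * k, 230 * k, 600, 30))$P_cm_per_s
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  for (mult in c(2, 3)) {
    expect_equal(permeability_coefficient(
      permeability_window(200, 100, 230, 600, 30 * mult))$P_cm_per_s,
      base * mult, tolerance = 1e-12)
    expect_equal(permeability_coefficient(
      permeability_window(200, 100, 200 + 30 * mult, 600, 30))$P_cm_per_s,
      base * mult, tolerance = 1e-12)
  }
})

test_that("time-series estimation applies the window rules", {
  ser <- generate_permeability_series(5e-7, d_um = 31, n_frames = 61,
                                      frame_interval_s = 15, seed = 1)
  est <- estimate_from_timeseries(ser$frames, ser$vessel_mask_window,
                                  ser$background, 15)
  expect_equal(est$delta_t, 900)
  expect_lt(abs(est$P_cm_per_s - 5e-7) / 5e-7, 0.01)
  expect_true(est$qc_flags$diameter_ok)
  # wide vessels are rejected under the 50-um selection rule
  wide <- generate_permeability_series(5e-7, d_um = 60, window_px = c(128, 64))
  expect_error(estimate_from_timeseries(wide$frames, wide$vessel_mask_window,
                                        wide$background, 15),
               "rejected")
  est_w <- estimate_from_timeseries(wide$frames, wide$vessel_mask_window,
                                    wide$background, 15, allow_wide = TRUE)
  expect_false(est_w$qc_flags$diameter_ok)
  expect_error(estimate_from_timeseries(ser$frames[1], ser$vessel_mask_window,
                                        ser$background, 15), "2 frames")
})

test_that("a background region can be supplied instead of a scalar", {
  ser <- generate_permeability_series(3e-7, d_um = 21, seed = 4)
  # designate the top rows (gel at baseline in the first frame) as background
  bg_region <- matrix(FALSE, 96, 64)
  bg_region[1:10, ] <- TRUE
  est <- estimate_from_timeseries(ser$frames, ser$vessel_mask_window,
                                  bg_region, 15)
  expect_lt(abs(est$P_cm_per_s - 3e-7) / 3e-7, 0.02)
})

test_that("noisy series are recovered within tolerance; regression variant agrees", {
  errs <- vapply(1:10, function(s) {
    ser <- generate_permeability_series(5e-7, d_um = 31, noise_sd_frac = 0.02,
                                        seed = s)
    est <- estimate_from_timeseries(ser$frames, ser$vessel_mask_window,
                                    ser$background, 15)
    abs(est$P_cm_per_s - 5e-7) / 5e-7
  }, numeric(1))
  expect_lte(stats::median(errs), 0.05)
  ser <- generate_permeability_series(5e-7, d_um = 31, noise_sd_frac = 0.02,
                                      seed = 99)
  ep <- estimate_from_timeseries(ser$frames, ser$vessel_mask_window,
                                 ser$background, 15)
  er <- estimate_from_timeseries(ser$frames, ser$vessel_mask_window,
                                 ser$background, 15, estimator = "regression")
  expect_lt(abs(er$P_cm_per_s - 5e-7) / 5e-7, 0.05)
  expect_equal(er$estimator, "regression")
  expect_equal(ep$estimator, "endpoint")
})
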