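# Microvascular permeability-coefficient estimation from windowed
# dye-efflux time-lapse data.
#
# The estimator assumes a perfused cylindrical vessel crossing a
# measurement window that also covers perivascular gel: intravascular
# fluorescence stays constant, and solute efflux raises the window-mean
# intensity linearly. The permeability coefficient is
#   P (cm/s) = 1/(I_i - I_b) * (I_f - I_i)/dt * d/4
# with I_i/I_f the window means at the initial/final time points, I_b the
# background level, dt the elapsed time in seconds and d the mean vessel
# diameter (carried in um, converted to cm exactly once inside the formula).
# Only vessels with d < 50 um are accepted, preserving the circular
# cross-section requirement of the formula.

#' Measure the mean vessel diameter in a window
#'
#' The vessel strip is skeletonized and the diameter is taken as twice the
#' mean Euclidean distance from the centerline to the vessel boundary. The
#' mask is edge-replicated before the distance transform so a vessel running
#' through the window border is not treated as ending there.
#'
#' @param vessel_mask_window `binary_mask` containing exactly one vessel
#'   strip.
#' @return Mean diameter in micrometers.
#' @export
measure_vessel_diameter <- function(vessel_mask_window) {
  stopifnot(inherits(vessel_mask_window, "binary_mask"))
  m <- vessel_mask_window$pixels
  abort_if(!any(m), "window contains no vessel")
  n_comp <- max(label_components(vessel_mask_window))
  abort_if(n_comp != 1L,
           sprintf("window must contain exactly one vessel (found %d components)",
                   n_comp))
  pad <- max(8L, min(dim(m)) %/% 2L)
  ri <- pmin(pmax(seq(1 - pad, nrow(m) + pad), 1), nrow(m))
  ci <- pmin(pmax(seq(1 - pad, ncol(m) + pad), 1), ncol(m))
  mp <- m[ri, ci]
  dist <- as.matrix(EBImage::distmap(mp * 1, metric = "euclidean"))
  sk <- zhang_suen_skeleton(mp)
  # keep only the part of the skeleton corresponding to the original window
  core <- matrix(FALSE, nrow(mp), ncol(mp))
  core[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))] <- TRUE
  sel <- sk & core
  if (!any(sel)) sel <- sk
  # distance is measured center-to-center, overshooting each boundary by
  # half a pixel: subtract one pixel so an odd-width strip is recovered
  # exactly
  (2 * mean(dist[sel]) - 1) * vessel_mask_window$pixel_size_um
}

#' Assemble a permeability measurement window
#'
#' @param I_i Mean window intensity at the initial time point.
#' @param I_b Background intensity (vessel-free region).
#' @param I_f Mean window intensity at the final time point.
#' @param delta_t Elapsed time between initial and final frames (s).
#' @param d_um Mean vessel diameter in the window (um).
#' @param qc_flags Named list of QC flags (e.g. `diameter_ok`).
#' @return An object of class `permeability_window`.
#' @export
permeability_window <- function(I_i, I_b, I_f, delta_t, d_um,
                                qc_flags = list()) {
  abort_if(!is_scalar_number(delta_t) || delta_t <= 0, "delta_t must be > 0")
  abort_if(!is_scalar_number(d_um) || d_um <= 0, "d must be > 0")
  abort_if(!is_scalar_number(I_i) || !is_scalar_number(I_b) ||
             !is_scalar_number(I_f), "intensities must be numbers")
  abort_if(I_i <= I_b,
           "I_i must exceed I_b (perfused vessel brighter than background)")
  structure(list(I_i = I_i, I_b = I_b, I_f = I_f, delta_t = delta_t,
                 d_um = d_um, qc_flags = qc_flags),
            class = "permeability_window")
}

#' Permeability coefficient of a measurement window
#'
#' Evaluates `P = 1/(I_i - I_b) * (I_f - I_i)/delta_t * d/4` with the
#' diameter converted from micrometers to centimeters. A negative result
#' (final dimmer than initial, e.g. photobleaching-dominated windows) is
#' returned with a QC flag rather than clipped.
#'
#' @param w A [permeability_window()].
#' @return List with `P_cm_per_s`, the echoed inputs, and `qc_flags`
#'   (gains `nonnegative_ok = FALSE` when P < 0).
#' @export
permeability_coefficient <- function(w) {
  stopifnot(inherits(w, "permeability_window"))
  d_cm <- w$d_um * 1e-4
  P <- (1 / (w$I_i - w$I_b)) * ((w$I_f - w$I_i) / w$delta_t) * (d_cm / 4)
  qc <- w$qc_flags
  qc$nonnegative_ok <- P >= 0
  list(P_cm_per_s = P, I_i = w$I_i, I_b = w$I_b, I_f = w$I_f,
       delta_t = w$delta_t, d_um = w$d_um, qc_flags = qc)
}

#' Estimate the permeability coefficient from a time-lapse window
#'
#' Computes `I_i` from the first frame, `I_f` from the last,
#' `delta_t = (n_frames - 1) * frame_interval_s`, the background from a
#' designated vessel-free region (or a supplied scalar), and the vessel
#' diameter from the mask. Windows with `d >= d_max_um` (50 um: the circular
#' cross-section selection rule) are rejected unless `allow_wide = TRUE`, in
#' which case the result carries `diameter_ok = FALSE`.
#'
#' @param frames List of `calibrated_image` windows (>= 2), in time order.
#' @param vessel_mask_window `binary_mask` of the vessel within the window.
#' @param background Either a scalar background intensity, or a logical
#'   matrix selecting a vessel-free region of the first frame.
#' @param frame_interval_s Seconds between consecutive frames.
#' @param d_max_um Diameter selection bound (default 50 um).
#' @param allow_wide Report wide-vessel windows instead of erroring.
#' @param estimator `"endpoint"` for the printed first-vs-last-frame
#'   difference, or `"regression"` for a least-squares slope over all frames
#'   (robustness variant, not part of the published procedure).
#' @return A [permeability_coefficient()] result plus `window` and
#'   `estimator`.
#' @export
estimate_from_timeseries <- function(frames, vessel_mask_window, background,
                                     frame_interval_s, d_max_um = 50,
                                     allow_wide = FALSE,
                                     estimator = c("endpoint", "regression")) {
  estimator <- match.arg(estimator)
  abort_if(!is.list(frames) || length(frames) < 2L,
           "need at least 2 frames")
  abort_if(!is_scalar_number(frame_interval_s) || frame_interval_s <= 0,
           "frame_interval_s must be > 0")
  means <- vapply(frames, function(f) mean(as_pixels(f)), numeric(1))
  I_i <- means[1]
  I_f <- means[length(means)]
  delta_t <- (length(frames) - 1) * frame_interval_s
  I_b <- if (is_scalar_number(background)) {
    background
  } else {
    bg <- as.matrix(background)
    abort_if(!any(bg > 0), "background region is empty")
    mean(as_pixels(frames[[1]])[bg > 0])
  }
  d_um <- measure_vessel_diameter(vessel_mask_window)
  diameter_ok <- d_um < d_max_um
  if (!diameter_ok && !allow_wide) {
    stop(sprintf(paste0("vessel diameter %.1f um >= %.0f um: window rejected ",
                        "(only vessels below the bound have the circular ",
                        "cross-section the formula assumes)"),
                 d_um, d_max_um), call. = FALSE)
  }
  if (estimator == "regression") {
    tt <- (seq_along(frames) - 1) * frame_interval_s
    slope <- stats::coef(stats::lm(means ~ tt))[["tt"]]
    I_f <- I_i + slope * delta_t
  }
  w <- permeability_window(I_i, I_b, I_f, delta_t, d_um,
                           qc_flags = list(diameter_ok = diameter_ok,
                                           window_placement_ok = TRUE))
  out <- permeability_coefficient(w)
  out$window <- w
  out$estimator <- estimator
  out
}
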