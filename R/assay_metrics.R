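# 2D assay quantifications: cell-shape circularity, corrected total cell
# fluorescence (CTCF), scratch-wound gap area, spheroid invasion ratio, and
# cytokine-array log2 fold changes.

#' Region measurement record
#'
#' @param area_um2 Region area (>= 0).
#' @param perimeter_um Region perimeter.
#' @param integrated_density Sum of intensities over the region.
#' @param mean_intensity Mean intensity over the region.
#' @param label Region label.
#' @return An object of class `region_measurement`.
#' @export
region_measurement <- function(area_um2, perimeter_um = NA_real_,
                               integrated_density = NA_real_,
                               mean_intensity = NA_real_, label = "") {
  abort_if(!is_scalar_number(area_um2) || area_um2 < 0, "area_um2 must be >= 0")
  structure(list(area_um2 = area_um2, perimeter_um = perimeter_um,
                 integrated_density = integrated_density,
                 mean_intensity = mean_intensity, label = label),
            class = "region_measurement")
}

#' Circularity of a measured region
#'
#' `4 * pi * area / perimeter^2`, clipped to at most 1.0. A value of 1
#' indicates a perfect circle; values approaching 0 an elongated morphology.
#'
#' @param region A [region_measurement()] (or anything with `area_um2` and
#'   `perimeter_um` fields).
#' @return Dimensionless circularity in (0, 1].
#' @export
circularity <- function(region) {
  abort_if(is.null(region$perimeter_um) || !is_scalar_number(region$perimeter_um) ||
             region$perimeter_um <= 0, "perimeter must be > 0")
  shape_circularity(region$area_um2, region$perimeter_um)
}

#' Corrected total cell fluorescence (CTCF)
#'
#' `CTCF = integrated density - (cell area * mean background intensity)`.
#' Negative values (cell dimmer than background) are reported, not floored:
#' they are informative QC.
#'
#' @param integrated_density Sum of intensities over the cell region.
#' @param cell_area Area of the selected cell (> 0; any fixed unit, as long
#'   as the integrated density uses the same pixel basis).
#' @param mean_background Mean background fluorescence intensity (>= 0).
#' @return CTCF value (may be negative).
#' @export
ctcf <- function(integrated_density, cell_area, mean_background) {
  abort_if(!is_scalar_number(cell_area) || cell_area <= 0,
           "cell_area must be > 0")
  abort_if(!is_scalar_number(mean_background) || mean_background < 0,
           "mean_background must be >= 0")
  integrated_density - cell_area * mean_background
}

#' Remaining scratch gap area as a percentage of the initial gap
#'
#' @param gap_mask_t `binary_mask` of the cell-free gap at time t.
#' @param gap_mask_0 `binary_mask` of the initial gap (non-empty), same
#'   geometry.
#' @return `100 * area(gap_t) / area(gap_0)`.
#' @export
gap_area_fraction <- function(gap_mask_t, gap_mask_0) {
  stopifnot(inherits(gap_mask_t, "binary_mask"),
            inherits(gap_mask_0, "binary_mask"))
  abort_if(!identical(dim(gap_mask_t$pixels), dim(gap_mask_0$pixels)),
           "gap masks must share geometry")
  a0 <- sum(gap_mask_0$pixels)
  abort_if(a0 == 0, "initial gap mask is empty")
  100 * sum(gap_mask_t$pixels) / a0
}

#' Detect the cell-free gap of a scratch assay image
#'
#' Convenience detector: cell-free regions of a phase-contrast scratch image
#' are smooth, so pixels whose local intensity variance falls below an
#' automatic (Otsu) split of the variance map are called gap. Manually
#' traced masks remain the reference path; this detector only removes the
#' tracing burden for well-behaved images.
#'
#' @param img `calibrated_image` of the scratch assay field.
#' @param window Half-width of the local-variance window (px).
#' @return A `binary_mask` of the detected gap.
#' @export
detect_gap_mask <- function(img, window = 5L) {
  stopifnot(inherits(img, "calibrated_image"))
  m <- img$pixels
  k <- matrix(1, 2 * window + 1, 2 * window + 1)
  k <- k / sum(k)
  mu <- conv_reflect(m, k)
  v <- pmax(conv_reflect(m^2, k) - mu^2, 0)
  thr <- otsu_threshold(v)$threshold
  if (is.na(thr)) {
    return(binary_mask(matrix(TRUE, nrow(m), ncol(m)), img$pixel_size_um,
                       provenance = "detect_gap_mask:constant"))
  }
  binary_mask(v <= thr, img$pixel_size_um, provenance = "detect_gap_mask")
}

#' Spheroid invasion-area ratio
#'
#' The invaded area divided by the initial spheroid area, optionally
#' normalized so the control-group mean maps to 1.0.
#'
#' @param invasion_area_um2 Invaded area (>= 0).
#' @param initial_spheroid_area_um2 Initial spheroid area (> 0).
#' @param control_mean Optional control-group mean ratio to normalize by.
#' @return The (optionally normalized) invasion ratio.
#' @export
invasion_ratio <- function(invasion_area_um2, initial_spheroid_area_um2,
                           control_mean = NULL) {
  abort_if(!is_scalar_number(initial_spheroid_area_um2) ||
             initial_spheroid_area_um2 <= 0,
           "initial spheroid area must be > 0")
  r <- invasion_area_um2 / initial_spheroid_area_um2
  if (!is.null(control_mean)) {
    abort_if(!is_scalar_number(control_mean) || control_mean <= 0,
             "control_mean must be > 0")
    r <- r / control_mean
  }
  r
}

#' Cytokine-array log2 fold change
#'
#' Log2 ratio of conditioned-medium to control mean spot intensities.
#' Duplicate spots should be averaged before calling (see
#' [average_duplicate_spots()]). Background subtraction is available but off
#' by default; a pseudocount can stabilize near-zero spots.
#'
#' @param mean_spot_intensity_cm Mean spot intensity, conditioned medium.
#' @param mean_spot_intensity_control Mean spot intensity, control.
#' @param background Background intensity subtracted from both (default 0).
#' @param pseudocount Added to both after background subtraction (default 0).
#' @return `log2(cm / control)`.
#' @export
cytokine_log2fc <- function(mean_spot_intensity_cm,
                            mean_spot_intensity_control,
                            background = 0, pseudocount = 0) {
  cm <- mean_spot_intensity_cm - background + pseudocount
  ctrl <- mean_spot_intensity_control - background + pseudocount
  abort_if(any(!is.finite(cm)) || any(!is.finite(ctrl)),
           "intensities must be finite")
  abort_if(any(ctrl <= 0) || any(cm <= 0),
           "intensities must be positive after background/pseudocount handling")
  log2(cm / ctrl)
}

#' Average duplicate cytokine spots
#'
#' @param intensities Numeric vector of replicate spot intensities.
#' @return Their mean.
#' @export
average_duplicate_spots <- function(intensities) {
  abort_if(length(intensities) == 0L, "no spot intensities supplied")
  mean(intensities)
}
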