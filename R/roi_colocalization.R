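# Spheroid-proximal analysis windows (tROI), vessel ROIs (vROI) and
# co-localization-based intravasation counting.
#
# Workflow per spheroid: fit an ellipse to the spheroid component, draw an
# axis-aligned square window whose side is 115% of the fitted major axis
# (tROI), restrict the segmented vessel mask to it (vROI), zero all cancer
# signal outside the vROI, Otsu-threshold what remains, and count connected
# particles passing the size (>= 50 um^2) and circularity ([0.5, 1.0])
# filters.

#' Extract per-spheroid square analysis windows (tROIs)
#'
#' Connected spheroid components above `min_spheroid_area_um2` each yield a
#' region of interest: an ellipse is fitted by second image moments and an
#' axis-aligned square window with side 115% of the fitted major axis is
#' centered on the ellipse center, clipped to the image bounds.
#'
#' @param spheroid_mask A `binary_mask` of spheroid regions.
#' @param min_spheroid_area_um2 Minimum component area to count as a
#'   spheroid (filters out stray cells/debris).
#' @param troi_scale Window side as a fraction of the major axis
#'   (default 1.15).
#' @return List of `spheroid_roi` objects, each with `spheroid_id`,
#'   `ellipse` (center, axes in um, orientation), `troi` (clipped bounds
#'   `top, left, bottom, right` plus nominal `side` in px) and `clipped`.
#' @export
extract_spheroid_rois <- function(spheroid_mask, min_spheroid_area_um2 = 500,
                                  troi_scale = 1.15) {
  stopifnot(inherits(spheroid_mask, "binary_mask"))
  abort_if(troi_scale <= 0, "troi_scale must be > 0")
  ps <- spheroid_mask$pixel_size_um
  regs <- measure_regions(spheroid_mask)
  regs <- regs[regs$area_um2 >= min_spheroid_area_um2, , drop = FALSE]
  if (nrow(regs) == 0L) return(list())
  H <- nrow(spheroid_mask$pixels); W <- ncol(spheroid_mask$pixels)
  lapply(seq_len(nrow(regs)), function(i) {
    r <- regs[i, ]
    side <- max(1L, round(troi_scale * r$major_um / ps))
    top <- round(r$centroid_row - (side - 1) / 2)
    left <- round(r$centroid_col - (side - 1) / 2)
    bottom <- top + side - 1L
    right <- left + side - 1L
    clipped <- top < 1 || left < 1 || bottom > H || right > W
    structure(
      list(spheroid_id = sprintf("sph%02d", r$label),
           ellipse = list(center_row = r$centroid_row,
                          center_col = r$centroid_col,
                          major_um = r$major_um, minor_um = r$minor_um,
                          orientation = r$orientation),
           troi = list(top = max(1L, top), left = max(1L, left),
                       bottom = min(H, bottom), right = min(W, right),
                       side = side),
           clipped = clipped, pixel_size_um = ps),
      class = "spheroid_roi")
  })
}

#' @export
print.spheroid_roi <- function(x, ...) {
  cat(sprintf("<spheroid_roi> %s: major %.1f um, tROI side %d px%s\n",
              x$spheroid_id, x$ellipse$major_um, x$troi$side,
              if (x$clipped) " (clipped)" else ""))
  invisible(x)
}

#' Crop an image or mask to a tROI window
#'
#' @param x `calibrated_image` or `binary_mask` sharing the geometry the
#'   tROI was extracted from.
#' @param troi A `spheroid_roi`.
#' @return Cropped object of the same class.
#' @export
crop_to_troi <- function(x, troi) {
  stopifnot(inherits(troi, "spheroid_roi"))
  b <- troi$troi
  if (inherits(x, "calibrated_image")) {
    abort_if(b$bottom > nrow(x$pixels) || b$right > ncol(x$pixels),
             "tROI does not fit the supplied image geometry")
    calibrated_image(x$pixels[b$top:b$bottom, b$left:b$right, drop = FALSE],
                     x$channel_role, x$pixel_size_um,
                     frame_index = x$frame_index, metadata = x$metadata)
  } else if (inherits(x, "binary_mask")) {
    abort_if(b$bottom > nrow(x$pixels) || b$right > ncol(x$pixels),
             "tROI does not fit the supplied mask geometry")
    binary_mask(x$pixels[b$top:b$bottom, b$left:b$right, drop = FALSE],
                x$pixel_size_um, provenance = x$provenance)
  } else {
    stop("x must be a calibrated_image or binary_mask", call. = FALSE)
  }
}

#' Restrict a vessel mask to a tROI (vROI)
#'
#' @param vessel_mask Whole-image vessel `binary_mask`.
#' @param troi A `spheroid_roi` from the same image geometry.
#' @return A `vessel_roi`: the cropped mask plus its vessel area in um^2.
#' @export
build_vessel_roi <- function(vessel_mask, troi) {
  stopifnot(inherits(vessel_mask, "binary_mask"),
            inherits(troi, "spheroid_roi"))
  abort_if(abs(vessel_mask$pixel_size_um - troi$pixel_size_um) > 1e-9,
           "vessel mask and tROI calibrations differ")
  cropped <- crop_to_troi(vessel_mask, troi)
  structure(
    list(spheroid_id = troi$spheroid_id, mask = cropped,
         vessel_area_um2 = area_um2(sum(cropped$pixels),
                                    cropped$pixel_size_um),
         troi = troi),
    class = "vessel_roi")
}

#' Otsu intensity threshold
#'
#' Threshold maximizing the between-class variance of the intensity
#' histogram; foreground is strictly above the returned value.
#'
#' @param img `calibrated_image`, matrix, or numeric vector of intensities.
#' @return List with `threshold` (NA for a constant input, with a warning)
#'   and `effectiveness` (between-class over total variance at the optimum,
#'   in `[0, 1]`).
#' @export
otsu_threshold <- function(img) {
  v <- if (is.numeric(img) && is.null(dim(img))) img else as.vector(as_pixels(img))
  if (diff(range(v)) == 0) {
    warning("constant window: no Otsu threshold exists, returning NA")
    return(list(threshold = NA_real_, effectiveness = 0))
  }
  h <- intensity_histogram(matrix(v, 1))
  lv <- h$levels; ct <- h$counts
  n <- sum(ct)
  w0 <- cumsum(ct)
  s0 <- cumsum(ct * lv)
  mu_t <- s0[length(s0)] / n
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (s0[length(s0)] - s0) / w1, 0)
  sb2 <- w0 * w1 * (mu0 - mu1)^2 / n^2
  k <- length(lv) - 1L
  sb2 <- sb2[seq_len(k)]
  best <- which.max(sb2)
  # ties form a plateau when no observations fall between the classes;
  # take the middle of the contiguous optimal run (ImageJ behavior)
  tol <- max(sb2[best] * 1e-12, .Machine$double.eps)
  lo_run <- best
  while (lo_run > 1L && sb2[lo_run - 1L] >= sb2[best] - tol) lo_run <- lo_run - 1L
  hi_run <- best
  while (hi_run < k && sb2[hi_run + 1L] >= sb2[best] - tol) hi_run <- hi_run + 1L
  best <- (lo_run + hi_run) %/% 2L
  total_var <- sum(ct * (lv - mu_t)^2) / n
  list(threshold = lv[best],
       effectiveness = if (total_var > 0) sb2[best] / total_var else 0)
}

#' Count intravasation events inside a vessel ROI
#'
#' Implements the co-localization counting step: (1) cancer signal outside
#' the vROI is excluded; (2) the remaining in-vROI intensities are
#' Otsu-thresholded; (3) 8-connected components are labeled; (4) components
#' with area >= `min_area_um2` and circularity in
#' `[circ_min, circ_max]` are counted as intravasation events. The result is
#' invariant to any change of cancer pixels outside the vROI mask.
#'
#' @param cancer_img `calibrated_image` of the cancer channel cropped to the
#'   same tROI window as `vroi` (see [crop_to_troi()]).
#' @param vroi A [build_vessel_roi()] result.
#' @param min_area_um2 Minimum particle area (default 50 um^2).
#' @param circ_min,circ_max Circularity filter bounds (default 0.5 and 1.0).
#' @return An `event_count`: `spheroid_id`, `n_events`, `particles`
#'   (data frame of all candidate particles with a `passed_filters` column),
#'   and `condition_label`.
#' @export
count_intravasation_events <- function(cancer_img, vroi, min_area_um2 = 50,
                                       circ_min = 0.5, circ_max = 1.0) {
  stopifnot(inherits(cancer_img, "calibrated_image"),
            inherits(vroi, "vessel_roi"))
  abort_if(!identical(dim(cancer_img$pixels), dim(vroi$mask$pixels)),
           "cancer window and vROI geometries differ")
  abort_if(abs(cancer_img$pixel_size_um - vroi$mask$pixel_size_um) > 1e-9,
           "cancer window and vROI calibrations differ")
  ps <- cancer_img$pixel_size_um
  inside <- vroi$mask$pixels
  empty <- data.frame(spheroid_id = character(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), circularity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      passed_filters = logical(0))
  mk <- function(particles) {
    passed <- particles[particles$passed_filters, , drop = FALSE]
    structure(list(spheroid_id = vroi$spheroid_id,
                   n_events = nrow(passed), particles = particles,
                   condition_label = ""),
              class = "event_count")
  }
  if (!any(inside)) return(mk(empty))
  vals <- cancer_img$pixels[inside]
  if (diff(range(vals)) == 0) {
    warning("constant cancer signal inside vROI: no particles segmented")
    return(mk(empty))
  }
  thr <- otsu_threshold(vals)$threshold
  fg <- inside & (cancer_img$pixels > thr)
  if (!any(fg)) return(mk(empty))
  regs <- measure_regions(binary_mask(fg, ps, provenance = "cancer_in_vroi"))
  particles <- data.frame(
    spheroid_id = vroi$spheroid_id,
    area_um2 = regs$area_um2, perimeter_um = regs$perimeter_um,
    circularity = regs$circularity,
    centroid_row = regs$centroid_row, centroid_col = regs$centroid_col,
    passed_filters = regs$area_um2 >= min_area_um2 &
      regs$circularity >= circ_min & regs$circularity <= circ_max)
  mk(particles)
}

#' @export
print.event_count <- function(x, ...) {
  cat(sprintf("<event_count> %s: %d events (%d candidate particles)\n",
              x$spheroid_id, x$n_events, nrow(x$particles)))
  invisible(x)
}

#' Summarize intravasation events per experimental group
#'
#' @param counts List of `event_count` objects.
#' @param group_labels Character vector, one group label per count (taken
#'   from `condition_label` when omitted).
#' @return List with `summary` (per group: n spheroids, mean, SD, median
#'   events per spheroid; SD is `NA` for a single spheroid) and
#'   `per_spheroid` (long-format table suitable for external statistics).
#' @export
summarize_events <- function(counts, group_labels = NULL) {
  abort_if(length(counts) == 0L, "need at least one event count")
  if (is.null(group_labels)) {
    group_labels <- vapply(counts, function(x) x$condition_label, character(1))
  }
  abort_if(length(group_labels) != length(counts),
           "one group label per event count required")
  per <- data.frame(
    spheroid_id = vapply(counts, function(x) x$spheroid_id, character(1)),
    group = group_labels,
    n_events = vapply(counts, function(x) as.integer(x$n_events), integer(1)))
  groups <- unique(group_labels)
  rows <- lapply(groups, function(g) {
    v <- per$n_events[per$group == g]
    if (length(v) == 0L) {
      warning(sprintf("group '%s' is empty and was omitted", g))
      return(NULL)
    }
    data.frame(group = g, n_spheroids = length(v), mean_events = mean(v),
               sd_events = if (length(v) > 1L) stats::sd(v) else NA_real_,
               median_events = stats::median(v))
  })
  list(summary = do.call(rbind, rows), per_spheroid = per)
}
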