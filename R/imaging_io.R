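# Calibrated images, binary masks, and file I/O.
#
# Every downstream area/length computation is calibration-aware: a
# CalibratedImage carries the pixel size in micrometers per pixel, and the
# 50 um^2 particle filter, tROI sizes, vessel diameters and tubule lengths
# are all converted through it. Coordinate convention used throughout the
# package: row-major matrices, origin at top-left, 1-based indices (R),
# closed ROI bounds [top, top+side-1] x [left, left+side-1].

CHANNEL_ROLES <- c("phase", "gfp", "cancer", "other")

#' Create a calibrated microscopy image
#'
#' Wraps a 2D intensity matrix together with its channel role and spatial
#' calibration. All absolute areas and lengths computed by the package are
#' derived from `pixel_size_um`.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param channel_role One of `"phase"`, `"gfp"`, `"cancer"`, `"other"`.
#' @param pixel_size_um Pixel size in micrometers per pixel (> 0).
#' @param frame_index Optional integer frame index for time-lapse series.
#' @param metadata Optional named list of free-form provenance.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, channel_role = "other", pixel_size_um = 1,
                             frame_index = NULL, metadata = list()) {
  abort_if(!is.matrix(pixels) || length(pixels) == 0L,
           "pixels must be a non-empty matrix")
  abort_if(any(!is.finite(pixels)) || any(pixels < 0),
           "pixels must be finite and non-negative")
  abort_if(!channel_role %in% CHANNEL_ROLES,
           sprintf("channel_role must be one of: %s",
                   paste(CHANNEL_ROLES, collapse = ", ")))
  abort_if(!is_scalar_number(pixel_size_um) || pixel_size_um <= 0,
           "pixel_size_um must be a positive number")
  structure(
    list(pixels = pixels, channel_role = channel_role,
         pixel_size_um = as.numeric(pixel_size_um),
         frame_index = frame_index, metadata = metadata),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %dx%d px, role=%s, %.4g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$channel_role,
              x$pixel_size_um))
  invisible(x)
}

#' Create a binary mask
#'
#' @param pixels Logical matrix (numeric input is coerced with `> 0`).
#' @param pixel_size_um Pixel size in micrometers per pixel, propagated
#'   unchanged from the source image.
#' @param provenance Short description of the producing operation.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size_um = 1, provenance = "") {
  abort_if(!is.matrix(pixels) || length(pixels) == 0L,
           "pixels must be a non-empty matrix")
  if (!is.logical(pixels)) {
    m <- pixels > 0
  } else {
    m <- pixels
  }
  abort_if(anyNA(m), "mask must not contain NA")
  abort_if(!is_scalar_number(pixel_size_um) || pixel_size_um <= 0,
           "pixel_size_um must be a positive number")
  structure(
    list(pixels = m, pixel_size_um = as.numeric(pixel_size_um),
         provenance = provenance),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %dx%d px, %d foreground (%.1f%%), %.4g um/px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' Convert a pixel count to an area in square micrometers
#'
#' @param pixel_count Non-negative pixel count.
#' @param pixel_size_um Pixel size in micrometers per pixel.
#' @return `pixel_count * pixel_size_um^2`.
#' @export
area_um2 <- function(pixel_count, pixel_size_um) {
  abort_if(any(!is.finite(pixel_count)) || any(pixel_count < 0),
           "pixel_count must be >= 0")
  abort_if(!is_scalar_number(pixel_size_um) || pixel_size_um <= 0,
           "pixel_size_um must be a positive number")
  pixel_count * pixel_size_um^2
}

#' Load a calibrated image from TIFF or PNG
#'
#' Reads a single- or multi-page 2D raster. Intensities are preserved without
#' rescaling (16-bit TIFF pages come back as the original integer counts).
#' The pixel size is part of the experiment configuration: the paper's source
#' images carry no deposited calibration, so `pixel_size_um` must be supplied;
#' when the TIFF carries resolution tags they are recorded in `metadata` but
#' the supplied value wins.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param channel_role Channel role, recycled across pages, or a vector with
#'   one role per page for multi-page stacks.
#' @param pixel_size_um Pixel size in micrometers per pixel (> 0).
#' @return A `calibrated_image`, or a list of them for a multi-page TIFF.
#' @export
load_image <- function(path, channel_role = "other", pixel_size_um = 1) {
  abort_if(!is_scalar_number(pixel_size_um) || pixel_size_um <= 0,
           "pixel_size_um must be a positive number")
  abort_if(!file.exists(path), sprintf("cannot read image file: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  } else if (ext == "png") {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L) p <- p[, , 1]
    pages <- list(round(p * 65535))
  } else {
    stop(sprintf("unsupported image format '%s' for %s", ext, path),
         call. = FALSE)
  }
  roles <- rep_len(channel_role, length(pages))
  out <- lapply(seq_along(pages), function(i) {
    px <- pages[[i]]
    if (length(dim(px)) == 3L) px <- px[, , 1]
    info <- attributes(pages[[i]])
    meta <- list(path = path, page = i)
    if (!is.null(info$x.resolution)) meta$tiff_x_resolution <- info$x.resolution
    calibrated_image(px, roles[i], pixel_size_um,
                     frame_index = if (length(pages) > 1L) i else NULL,
                     metadata = meta)
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Save calibrated images as a (multi-page) 16-bit TIFF
#'
#' Integer intensities in `[0, 65535]` round-trip exactly through
#' [load_image()]. Non-integer intensities are rounded with a warning.
#'
#' @param images A `calibrated_image` or list of them (shared geometry).
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
save_image <- function(images, path) {
  if (inherits(images, "calibrated_image")) images <- list(images)
  planes <- lapply(images, function(im) {
    px <- im$pixels
    if (any(px != round(px))) {
      warning("non-integer intensities rounded for 16-bit TIFF storage")
      px <- round(px)
    }
    abort_if(any(px < 0 | px > 65535),
             "intensities outside [0, 65535] cannot be stored as 16-bit TIFF")
    px / 65535
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Save a binary mask as an 8-bit {0, 255} TIFF
#'
#' @param mask A `binary_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  tiff::writeTIFF(ifelse(mask$pixels, 1, 0), path, bits.per.sample = 8L)
  invisible(path)
}

#' Load a {0, 255} mask TIFF as a binary mask
#'
#' @param path Path to a mask TIFF written by [save_mask()].
#' @param pixel_size_um Pixel size in micrometers per pixel.
#' @return A `binary_mask`.
#' @export
load_mask <- function(path, pixel_size_um = 1) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  binary_mask(px > 0, pixel_size_um, provenance = path)
}
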