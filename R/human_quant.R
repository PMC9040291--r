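#' Vessel / cellular threshold pair
#'
#' The dual-threshold workflow classifies AQP4-channel pixels of an ROI into
#' a *vessel* class (intensity at or above `vessel_threshold`, the bright
#' perivascular endfoot/vessel-edge signal) and a *cellular* class
#' (intensity in the half-open band `[cellular_threshold,
#' vessel_threshold)`, the astroglial fine-process signal). The cellular
#' threshold must lie strictly below the vessel threshold.
#'
#' @param vessel_threshold,cellular_threshold intensities in AU.
#' @return a `ThresholdPair` list.
#' @export
threshold_pair <- function(vessel_threshold, cellular_threshold) {
  if (cellular_threshold < 0 || vessel_threshold < 0) {
    stop("thresholds must be >= 0")
  }
  if (cellular_threshold >= vessel_threshold) {
    stop("cellular_threshold must be < vessel_threshold")
  }
  structure(list(vessel_threshold = vessel_threshold,
                 cellular_threshold = cellular_threshold),
            class = "ThresholdPair")
}

#' Place square ROIs over a section image
#'
#' Places non-overlapping square ROIs of `roi_px` pixels, assigned to the
#' requested region tags (e.g. 6 `gray` + 6 `white` for the frontal cortex
#' layout). Placement is on a shuffled grid so that a fixed `seed` gives
#' identical coordinates across runs; explicit coordinates can instead be
#' supplied downstream as a data.frame.
#'
#' @param image an [image2d()] (or a matrix) defining the available extent.
#' @param layout character vector of region tags, one per requested ROI.
#' @param roi_px ROI side length in pixels (default 1000).
#' @param seed RNG seed for the shuffled placement.
#' @return data.frame with columns `x`, `y` (0-based pixel offsets),
#'   `width_px`, `height_px`, `label`.
#' @export
place_rois <- function(image, layout, roi_px = 1000, seed = 1L) {
  d <- if (inherits(image, "Image2D")) dim(image) else dim(image)
  h <- d[1L]; w <- d[2L]
  nx <- w %/% roi_px
  ny <- h %/% roi_px
  n_max <- nx * ny
  n <- length(layout)
  if (n_max < n) {
    stop(sprintf(
      "image of %d x %d px holds at most %d non-overlapping %d-px ROIs; %d requested",
      h, w, n_max, roi_px, n))
  }
  cells <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  pick <- with_seed(seed, sample.int(nrow(cells), n))
  data.frame(x = cells$ix[pick] * roi_px, y = cells$iy[pick] * roi_px,
             width_px = roi_px, height_px = roi_px, label = layout,
             stringsAsFactors = FALSE)
}

#' Crop one ROI from an image channel
#' @param channel numeric matrix (rows = y, cols = x).
#' @param roi one row of a [place_rois()] data.frame.
#' @return numeric matrix.
#' @export
crop_roi <- function(channel, roi) {
  channel[(roi$y + 1L):(roi$y + roi$height_px),
          (roi$x + 1L):(roi$x + roi$width_px), drop = FALSE]
}

#' Automatic vessel/cellular threshold selection
#'
#' The reference workflow selected both thresholds manually (blinded); this
#' automation reproduces the structure of that choice as an upper-percentile
#' pair: the vessel threshold at the 99.5th intensity percentile (the bright
#' vessel-edge tail) and the cellular threshold at the 90th percentile.
#' Both values are returned and can be overridden by a manual
#' [threshold_pair()].
#'
#' @param roi_image numeric matrix of ROI intensities.
#' @param vessel_quantile,cellular_quantile percentile positions in (0, 1).
#' @return a [threshold_pair()].
#' @export
auto_thresholds <- function(roi_image, vessel_quantile = 0.995,
                            cellular_quantile = 0.90) {
  v <- as.numeric(roi_image)
  if (stats::var(v) == 0) {
    stop("ROI has zero intensity variance; thresholds are undefined")
  }
  # type 1 (inverted ECDF): thresholds are attained pixel values, never
  # interpolated between intensity levels
  q <- stats::quantile(v, c(cellular_quantile, vessel_quantile), names = FALSE,
                       type = 1)
  if (q[1L] >= q[2L]) {
    stop("percentile thresholds coincide; supply a manual threshold pair")
  }
  threshold_pair(vessel_threshold = q[2L], cellular_threshold = q[1L])
}

#' Dual-threshold AQP4 measurement of one ROI
#'
#' Computes the mean unthresholded intensity, the cellular area coverage
#' (fraction of pixels at or above the cellular threshold — a superset that
#' includes the vessel class), and the polarization ratio: mean intensity
#' of the vessel class divided by mean intensity of the cellular class
#' (pixels in `[cellular_threshold, vessel_threshold)`). An empty vessel or
#' cellular class makes the ratio undefined (`NA` with `undefined = TRUE`);
#' undefined measures propagate as missing values, they are never imputed.
#'
#' @param roi_image numeric matrix of ROI intensities (AU).
#' @param thresholds a [threshold_pair()].
#' @return list of class `HumanROIMeasures`: `mean_if`,
#'   `cellular_area_coverage`, `polarization_ratio`, `undefined`,
#'   `n_vessel_px`, `n_cellular_px`.
#' @export
measure_roi_aqp4 <- function(roi_image, thresholds) {
  stopifnot(inherits(thresholds, "ThresholdPair"))
  v <- as.numeric(roi_image)
  vt <- thresholds$vessel_threshold
  ct <- thresholds$cellular_threshold
  vessel <- v[v >= vt]
  cellular <- v[v >= ct & v < vt]
  undefined <- length(vessel) == 0L || length(cellular) == 0L
  structure(list(
    mean_if = mean(v),
    cellular_area_coverage = sum(v >= ct) / length(v),
    polarization_ratio = if (undefined) NA_real_ else mean(vessel) / mean(cellular),
    undefined = undefined,
    n_vessel_px = length(vessel),
    n_cellular_px = length(cellular),
    thresholds = thresholds
  ), class = "HumanROIMeasures")
}

#' P-tau-positive soma density per square millimeter
#'
#' Converts a soma count per ROI to counts/mm^2, or — given an ROI image of
#' the p-tau channel — detects somata first as bright blobs: pixels above
#' the midpoint between the ROI median and its robust maximum (the
#' `intensity_quantile` percentile), then connected components with area
#' inside `[min_area_um2, max_area_um2]`.
#'
#' @param count integer soma count (mutually exclusive with `roi_image`).
#' @param roi_image numeric matrix of the p-tau channel.
#' @param pixel_size_um micrometers per pixel; required, never defaulted.
#' @param intensity_quantile robust-maximum percentile (default 0.995).
#' @param min_area_um2,max_area_um2 soma area gate in um^2 (defaults 20 and
#'   400, spanning neuronal soma cross-sections).
#' @param width_px,height_px ROI extent in pixels; required on the
#'   count-only path, taken from `roi_image` otherwise.
#' @return list: `count`, `area_mm2`, `density_per_mm2`.
#' @export
ptau_density <- function(count = NULL, roi_image = NULL, pixel_size_um,
                         width_px = NULL, height_px = NULL,
                         intensity_quantile = 0.995, min_area_um2 = 20,
                         max_area_um2 = 400) {
  if (missing(pixel_size_um) || is.null(pixel_size_um)) {
    stop("`pixel_size_um` is required; no default is assumed")
  }
  stopifnot(pixel_size_um > 0)
  if (is.null(count) == is.null(roi_image)) {
    stop("supply exactly one of `count` or `roi_image`")
  }
  if (!is.null(roi_image)) {
    v <- as.numeric(roi_image)
    # midpoint between the background (median) and the soma amplitude
    # (robust maximum): insensitive to how much of the ROI the somata cover
    thr <- (stats::median(v) + stats::quantile(v, intensity_quantile,
                                               names = FALSE)) / 2
    lab <- EBImage::bwlabel(EBImage::Image(t(roi_image >= thr) * 1))
    sizes <- tabulate(as.integer(lab))
    areas <- sizes * pixel_size_um^2
    count <- sum(areas >= min_area_um2 & areas <= max_area_um2)
    height_px <- nrow(roi_image)
    width_px <- ncol(roi_image)
  } else if (is.null(width_px) || is.null(height_px)) {
    stop("count-only path needs `width_px` and `height_px`")
  }
  stopifnot(count >= 0)
  area_mm2 <- width_px * height_px * pixel_size_um^2 * 1e-6
  list(count = as.integer(count), area_mm2 = area_mm2,
       density_per_mm2 = count / area_mm2)
}

#' Aggregate per-ROI measures to one per-subject, per-region value
#'
#' Arithmetic mean over the available ROIs of a region, after dropping
#' excluded (e.g. out-of-focus) and undefined ROIs; mirrors averaging the 6
#' cortical gray (or white) matter ROIs to a single subject value. Records
#' how many ROIs entered the mean; zero valid ROIs yields a missing value
#' with the reason.
#'
#' @param values numeric vector of per-ROI values (NA = undefined).
#' @param excluded logical vector flagging ROIs excluded before analysis.
#' @return list: `mean`, `n_used`, `n_total`, `reason` (NULL when defined).
#' @export
aggregate_subject <- function(values, excluded = rep(FALSE, length(values))) {
  stopifnot(length(values) == length(excluded))
  keep <- !excluded & !is.na(values)
  if (!any(keep)) {
    return(list(mean = NA_real_, n_used = 0L, n_total = length(values),
                reason = "no valid ROI measures (all excluded or undefined)"))
  }
  list(mean = mean(values[keep]), n_used = sum(keep),
       n_total = length(values), reason = NULL)
}
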