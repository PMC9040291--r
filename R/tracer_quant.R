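#' Thresholded tracer area coverage per brain region
#'
#' Applies one uniform intensity threshold (the same value for every animal
#' and slice of an experiment) to the tracer channel and reports, per
#' region mask, the covered area, the region area, and the coverage
#' fraction. An empty region mask yields a missing value with a message.
#'
#' @param tracer an [image2d()] with a `tracer` channel, or a numeric
#'   matrix (then `pixel_size_um` is required).
#' @param masks named list of logical region masks (as from
#'   [make_region_masks()]); a `whole` mask, if present, is measured too.
#' @param threshold uniform intensity threshold in AU.
#' @param pixel_size_um micrometers per pixel for a bare matrix.
#' @param slice_id optional identifier copied into the output.
#' @return data.frame of class `TracerSliceMeasures`: `slice_id`, `region`,
#'   `region_area_mm2`, `covered_mm2`, `fraction`, `threshold`.
#' @export
tracer_coverage <- function(tracer, masks, threshold, pixel_size_um = NULL,
                            slice_id = NA) {
  if (inherits(tracer, "Image2D")) {
    psz <- tracer$pixel_size_um
    tracer <- get_channel(tracer, "tracer")
  } else {
    if (is.null(pixel_size_um)) stop("pixel_size_um required for bare matrix")
    psz <- pixel_size_um
  }
  stopifnot(is.list(masks), !is.null(names(masks)))
  px_mm2 <- psz^2 * 1e-6
  hot <- tracer >= threshold
  out <- do.call(rbind, lapply(names(masks), function(rn) {
    m <- masks[[rn]]
    n <- sum(m)
    if (n == 0L) {
      message(sprintf("region '%s': empty mask, coverage missing", rn))
      return(data.frame(slice_id = slice_id, region = rn,
                        region_area_mm2 = 0, covered_mm2 = NA_real_,
                        fraction = NA_real_, threshold = threshold))
    }
    cov_px <- sum(hot & m)
    data.frame(slice_id = slice_id, region = rn,
               region_area_mm2 = n * px_mm2, covered_mm2 = cov_px * px_mm2,
               fraction = cov_px / n, threshold = threshold)
  }))
  class(out) <- c("TracerSliceMeasures", class(out))
  out
}

#' Integrate tracer coverage across coronal slices
#'
#' Area-weighted integration per region over the available slices:
#' integrated coverage = sum(covered area) / sum(region area). Animals with
#' excluded (e.g. out-of-focus) slices are integrated over the remaining
#' slices; a region missing from every slice stays missing.
#'
#' @param measures a data.frame of stacked [tracer_coverage()] results
#'   (or a list of them, which is row-bound).
#' @param expected_slices optional vector of expected slice ids; a message
#'   reports any that are absent.
#' @return data.frame: `region`, `covered_mm2`, `region_area_mm2`,
#'   `fraction`, `n_slices`.
#' @export
integrate_slices <- function(measures, expected_slices = NULL) {
  if (is.list(measures) && !is.data.frame(measures)) {
    measures <- do.call(rbind, measures)
  }
  stopifnot(all(c("slice_id", "region", "region_area_mm2", "covered_mm2") %in%
                  names(measures)))
  if (nrow(measures) == 0L) stop("no slice measures supplied")
  if (!is.null(expected_slices)) {
    missing_sl <- setdiff(expected_slices, unique(measures$slice_id))
    if (length(missing_sl)) {
      message(sprintf("integrating without slice(s): %s",
                      paste(missing_sl, collapse = ", ")))
    }
  }
  out <- do.call(rbind, lapply(split(measures, measures$region), function(d) {
    ok <- !is.na(d$covered_mm2)
    if (!any(ok)) {
      return(data.frame(region = d$region[1L], covered_mm2 = NA_real_,
                        region_area_mm2 = NA_real_, fraction = NA_real_,
                        n_slices = 0L))
    }
    data.frame(region = d$region[1L],
               covered_mm2 = sum(d$covered_mm2[ok]),
               region_area_mm2 = sum(d$region_area_mm2[ok]),
               fraction = sum(d$covered_mm2[ok]) / sum(d$region_area_mm2[ok]),
               n_slices = sum(ok))
  }))
  rownames(out) <- NULL
  out
}

#' Suggest a uniform tracer threshold
#'
#' The reference workflow used one manually chosen, unreported threshold
#' per experiment. This utility suggests half of the robust maximum (the
#' 99.9th percentile) pooled over the supplied tracer channels; the choice
#' is advisory and should be reviewed, then fixed for the whole experiment.
#'
#' @param tracers list of tracer matrices (or [image2d()]s).
#' @return suggested threshold in AU.
#' @export
suggest_tracer_threshold <- function(tracers) {
  vals <- unlist(lapply(tracers, function(tr) {
    if (inherits(tr, "Image2D")) tr <- get_channel(tr, "tracer")
    as.numeric(tr)
  }))
  stats::quantile(vals, 0.999, names = FALSE) / 2
}
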