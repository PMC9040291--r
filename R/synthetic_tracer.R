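#' Build the synthetic region-mask set for one coronal slice
#'
#' Draws a simple coronal-section layout: a `whole` tissue mask containing
#' four pairwise-disjoint subregion blocks (cortex band on top;
#' hippocampus, striatum and diencephalon blocks below). In `efflux` mode
#' each subregion is split at the tissue midline into ipsilateral /
#' contralateral halves (suffixes `_ipsi`, `_contra`). Masks are logical
#' matrices; these stand in for atlas-drawn region outlines, which in the
#' real workflow are inputs drawn once per atlas level.
#'
#' @param width_px,height_px slice raster size.
#' @param mode `"influx"` (whole-region masks) or `"efflux"` (midline split).
#' @return named list of logical matrices; `whole` is the union tissue mask.
#' @export
make_region_masks <- function(width_px = 240, height_px = 200,
                              mode = c("influx", "efflux")) {
  mode <- match.arg(mode)
  blank <- function() matrix(FALSE, nrow = height_px, ncol = width_px)
  rect <- function(r0, r1, c0, c1) {
    m <- blank()
    m[max(1, r0):min(height_px, r1), max(1, c0):min(width_px, c1)] <- TRUE
    m
  }
  mrow <- function(f) round(f * height_px)
  mcol <- function(f) round(f * width_px)
  regions <- list(
    cortex       = rect(mrow(0.05), mrow(0.25), mcol(0.10), mcol(0.90)),
    hippocampus  = rect(mrow(0.32), mrow(0.55), mcol(0.10), mcol(0.45)),
    striatum     = rect(mrow(0.32), mrow(0.55), mcol(0.55), mcol(0.90)),
    diencephalon = rect(mrow(0.62), mrow(0.90), mcol(0.25), mcol(0.75))
  )
  if (mode == "efflux") {
    mid <- mcol(0.5)
    left <- blank(); left[, seq_len(mid)] <- TRUE
    split_one <- function(m) list(ipsi = m & left, contra = m & !left)
    out <- list()
    for (nm in names(regions)) {
      s <- split_one(regions[[nm]])
      out[[paste0(nm, "_ipsi")]] <- s$ipsi
      out[[paste0(nm, "_contra")]] <- s$contra
    }
    regions <- out
  }
  whole <- Reduce(`|`, regions)
  c(list(whole = whole), regions)
}

#' Specification of a synthetic tracer slice series
#'
#' Defines the generative model for CSF tracer influx (intracisternal) or
#' interstitial efflux (intraparenchymal) imaging: one slice per bregma
#' coordinate, region masks per [make_region_masks()], and a planted
#' coverage fraction per slice and region. The tracer front fills each
#' region contiguously from its medial edge to the planted fraction, with
#' an exponential intensity decay of length `front_decay_um` beyond the
#' front.
#'
#' @param coverage data.frame with columns `bregma_mm`, `region`, `fraction`
#'   (fractions in \[0, 1\]); regions must match the mask names of `mode`.
#'   Alternatively a named numeric vector of per-region fractions recycled
#'   across the default bregma set.
#' @param mode `"influx"` (bregma set 1, 0, -1.5, -2.5, -3.5 mm) or
#'   `"efflux"` (2.5, 1.5, 0, -1, -2 mm).
#' @param width_px,height_px slice raster size.
#' @param pixel_size_um micrometers per pixel (default 10, whole-slice
#'   scanner sampling).
#' @param tracer_intensity front amplitude in AU.
#' @param front_decay_um decay length of the tracer front, micrometers.
#' @param noise_sigma Gaussian noise SD in AU.
#' @param seed RNG seed.
#' @return a `tracer_spec` list.
#' @export
tracer_spec <- function(coverage, mode = c("influx", "efflux"),
                        width_px = 240, height_px = 200, pixel_size_um = 10,
                        tracer_intensity = 100, front_decay_um = 10,
                        noise_sigma = 0, seed = 1L) {
  mode <- match.arg(mode)
  bregma <- if (mode == "influx") c(1, 0, -1.5, -2.5, -3.5) else
    c(2.5, 1.5, 0, -1, -2)
  region_names <- setdiff(names(make_region_masks(4, 4, mode)), "whole")
  if (!is.data.frame(coverage)) {
    coverage <- coverage_table(coverage, bregma_mm = bregma)
  }
  stopifnot(all(c("bregma_mm", "region", "fraction") %in% names(coverage)))
  if (any(coverage$fraction < 0 | coverage$fraction > 1)) {
    stop("coverage fractions must lie in [0, 1]")
  }
  if (!all(coverage$region %in% region_names)) {
    stop(sprintf("unknown region(s): %s; expected %s",
                 paste(setdiff(coverage$region, region_names), collapse = ", "),
                 paste(region_names, collapse = ", ")))
  }
  structure(list(coverage = coverage, mode = mode, bregma_mm = bregma,
                 width_px = width_px, height_px = height_px,
                 pixel_size_um = pixel_size_um,
                 tracer_intensity = tracer_intensity,
                 front_decay_um = front_decay_um,
                 noise_sigma = noise_sigma, seed = seed),
            class = "tracer_spec")
}

#' Helper: per-region coverage table from a named vector
#'
#' @param fractions named numeric vector (region -> fraction in \[0,1\]).
#' @param bregma_mm bregma coordinates to replicate over.
#' @return data.frame suitable for [tracer_spec()].
#' @export
coverage_table <- function(fractions, bregma_mm = c(1, 0, -1.5, -2.5, -3.5)) {
  stopifnot(!is.null(names(fractions)))
  out <- expand.grid(bregma_mm = bregma_mm, region = names(fractions),
                     stringsAsFactors = FALSE)
  out$fraction <- fractions[out$region]
  out
}

#' Generate synthetic tracer slices with ground truth coverage
#'
#' Renders one tracer-channel image per bregma coordinate. Within each
#' region the planted fraction of pixels (ordered by column, i.e. a
#' contiguous front advancing from the region's left edge) is set to the
#' front amplitude; intensity decays exponentially beyond the front; pixels
#' outside all regions stay at zero. Quantization of the front is at most
#' one pixel column.
#'
#' @param spec a [tracer_spec()].
#' @return list with `slices` (per slice: `image` ([image2d()], channel
#'   `tracer`), `masks`, `bregma_mm`) and `truth` (data.frame `bregma_mm`,
#'   `region`, `planted`, `realized` — realized is the rendered fraction
#'   after pixel quantization).
#' @export
generate_tracer_slices <- function(spec) {
  stopifnot(inherits(spec, "tracer_spec"))
  masks <- make_region_masks(spec$width_px, spec$height_px, spec$mode)
  region_names <- setdiff(names(masks), "whole")
  truth <- list()
  slices <- with_seed(spec$seed, lapply(seq_along(spec$bregma_mm), function(si) {
    b <- spec$bregma_mm[si]
    img <- matrix(0, nrow = spec$height_px, ncol = spec$width_px)
    for (rn in region_names) {
      row <- spec$coverage[spec$coverage$bregma_mm == b &
                             spec$coverage$region == rn, ]
      f <- if (nrow(row)) row$fraction[1L] else 0
      m <- masks[[rn]]
      idx <- which(m, arr.ind = TRUE)
      ord <- order(idx[, 2L], idx[, 1L])  # advance column by column
      n <- nrow(idx)
      k <- round(f * n)
      if (k > 0) {
        sel <- idx[ord[seq_len(k)], , drop = FALSE]
        img[sel] <- spec$tracer_intensity
      }
      if (k < n && k > 0 && spec$front_decay_um > 0) {
        front_col <- idx[ord[k], 2L]
        rest <- idx[ord[(k + 1L):n], , drop = FALSE]
        d_um <- pmax(rest[, 2L] - front_col, 0) * spec$pixel_size_um
        img[rest] <- spec$tracer_intensity * exp(-d_um / spec$front_decay_um)
      }
      truth[[length(truth) + 1L]] <<- data.frame(
        bregma_mm = b, region = rn, planted = f, realized = k / n)
    }
    if (spec$noise_sigma > 0) {
      img <- pmax(img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                               nrow = spec$height_px), 0)
    }
    list(image = image2d(list(tracer = img), spec$pixel_size_um),
         masks = masks, bregma_mm = b)
  }))
  list(slices = slices, truth = do.call(rbind, truth))
}
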