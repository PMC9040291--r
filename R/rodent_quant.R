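#' Classify a vessel by diameter
#'
#' Capillaries are vessels under 10 micrometers in diameter; larger vessels
#' are `large`. A diameter of exactly 10 um is classed `large` (the
#' strict-less capillary rule keeps the classification deterministic).
#'
#' @param diameter_um vessel diameter in micrometers (> 0).
#' @return `"capillary"` or `"large"`.
#' @export
classify_vessel <- function(diameter_um) {
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0)) {
    stop("diameter must be positive")
  }
  ifelse(diameter_um < 10, "capillary", "large")
}

#' Segment vessels from the lectin channel
#'
#' Thresholds the endothelial lectin channel (Otsu by default), closes the
#' lumen mask morphologically, labels connected components, and annotates
#' each component with its wall mask (mask boundary), center, principal
#' axis, inscribed-disk diameter (distance transform: `(2 * max - 1) *
#' pixel_size_um`, which is exact for rasterized strips), and the
#' capillary/large class. Near-circular components (axis ratio < 1.5) get
#' the image x-axis as profile axis, flagged via `near_circular`.
#'
#' @param image an [image2d()] with a lectin channel, or a numeric matrix
#'   (then `pixel_size_um` is required).
#' @param channel channel name (default `"lectin"`).
#' @param threshold manual lumen threshold in AU; `NULL` for Otsu.
#' @param min_area_px drop components smaller than this (default 9).
#' @param pixel_size_um pixel size when `image` is a bare matrix.
#' @return list of `VesselAnnotation` objects: `id`, `lumen` (logical
#'   matrix), `wall` (logical matrix), `center_px` (x, y), `axis_xy` (unit
#'   vector of the vessel axis), `diameter_um`, `vessel_class`,
#'   `near_circular`. An empty lectin mask yields an empty list.
#' @export
segment_vessels <- function(image, channel = "lectin", threshold = NULL,
                            min_area_px = 9L, pixel_size_um = NULL) {
  if (inherits(image, "Image2D")) {
    lectin <- get_channel(image, channel)
    psz <- image$pixel_size_um
  } else {
    lectin <- image
    if (is.null(pixel_size_um)) stop("pixel_size_um required for bare matrix")
    psz <- pixel_size_um
  }
  mx <- max(lectin)
  if (mx <= 0 || stats::var(as.numeric(lectin)) == 0) return(list())
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(EBImage::Image(lectin / mx), range = c(0, 1)) * mx
  }
  mask <- lectin >= threshold
  if (!any(mask)) return(list())
  mask <- EBImage::closing(EBImage::Image(mask * 1),
                           EBImage::makeBrush(5, shape = "disc"))
  lab <- EBImage::bwlabel(mask)
  labm <- matrix(as.integer(lab), nrow = nrow(lectin))
  out <- list()
  for (i in seq_len(max(labm))) {
    lum <- labm == i
    if (sum(lum) < min_area_px) next
    dm <- as.matrix(EBImage::distmap(EBImage::Image(lum * 1)))
    idx <- which(lum, arr.ind = TRUE)
    center <- c(x = mean(idx[, 2L]), y = mean(idx[, 1L]))
    # principal axis from the second moments of the lumen pixels
    cc <- cbind(idx[, 2L] - center["x"], idx[, 1L] - center["y"])
    cv <- crossprod(cc) / nrow(cc)
    eg <- eigen(cv, symmetric = TRUE)
    axis_ratio <- sqrt(max(eg$values[1L], 1e-12) / max(eg$values[2L], 1e-12))
    near_circular <- axis_ratio < 1.5
    # inscribed-disk width is exact for rasterized strips; for near-circular
    # lumens the area-equivalent diameter avoids the sub-pixel center offset
    # of the distance transform
    diameter_um <- if (near_circular) {
      2 * sqrt(sum(lum) / pi) * psz
    } else {
      (2 * max(dm) - 1) * psz
    }
    axis_xy <- if (near_circular) c(0, 1) else eg$vectors[, 1L]
    axis_xy <- axis_xy / sqrt(sum(axis_xy^2))
    wall <- lum & !as.logical(as.matrix(
      EBImage::erode(EBImage::Image(lum * 1),
                     EBImage::makeBrush(3, shape = "box"))))
    out[[length(out) + 1L]] <- structure(
      list(id = length(out) + 1L, lumen = lum, wall = wall,
           center_px = unname(center), axis_xy = unname(axis_xy),
           diameter_um = diameter_um,
           vessel_class = classify_vessel(diameter_um),
           near_circular = near_circular),
      class = "VesselAnnotation")
  }
  out
}

# Distance (um) from each pixel center to the wall of the given lumen mask:
# distmap of the tissue (non-lumen) region gives the pixel distance to the
# nearest lumen pixel; subtracting half a pixel centers the estimate on the
# analytic wall. Optionally computed on a zero-padded canvas so that
# annulus completeness near image borders can be judged.
wall_distance_um <- function(lumen, pixel_size_um, pad_px = 0L) {
  if (pad_px > 0L) {
    h <- nrow(lumen); w <- ncol(lumen)
    big <- matrix(FALSE, h + 2L * pad_px, w + 2L * pad_px)
    big[pad_px + seq_len(h), pad_px + seq_len(w)] <- lumen
    lumen <- big
  }
  dm <- as.matrix(EBImage::distmap(EBImage::Image((!lumen) * 1)))
  (dm - 0.5) * pixel_size_um
}

#' Capillary endfoot vs neuropil AQP4 intensities
#'
#' Measures the mean AQP4 intensity in the perivascular endfoot annulus
#' (0 to `band_um` outside the wall of one capillary) and in a neuropil
#' reference annulus remote from all vessels (`neuropil_range_um`,
#' default 5-15 um, which automatically excludes every vessel's endfoot
#' band). Annuli are eroded by `guard_px` pixels at each radial edge so
#' that wall-quantization pixels do not dilute compartment means. If less
#' than half of the endfoot annulus lies inside the image, the vessel is
#' skipped (`NULL` with a message).
#'
#' @param aqp4 numeric matrix of the AQP4 channel.
#' @param vessel a `VesselAnnotation` of class capillary.
#' @param all_lumen logical matrix of every vessel lumen in the field
#'   (defaults to this vessel's lumen only).
#' @param band_um endfoot band width (default 1.5 um).
#' @param neuropil_range_um reference annulus, um from any wall.
#' @param pixel_size_um micrometers per pixel.
#' @param guard_px quantization guard at annulus edges (default 1).
#' @param min_fraction minimum in-image fraction of the endfoot annulus.
#' @return list: `pv_endfoot_if`, `neuropil_if`, `n_endfoot_px`,
#'   `n_neuropil_px`, `ratio`; or `NULL` when skipped.
#' @export
capillary_compartments <- function(aqp4, vessel, all_lumen = NULL,
                                   band_um = 1.5,
                                   neuropil_range_um = c(5, 15),
                                   pixel_size_um, guard_px = 1,
                                   min_fraction = 0.5) {
  stopifnot(inherits(vessel, "VesselAnnotation"))
  if (vessel$vessel_class != "capillary") {
    stop("capillary_compartments expects a capillary annotation")
  }
  psz <- pixel_size_um
  if (is.null(all_lumen)) all_lumen <- vessel$lumen
  g <- guard_px * psz
  pad <- ceiling(band_um / psz) + 2L
  d_pad <- wall_distance_um(vessel$lumen, psz, pad_px = pad)
  in_band_pad <- d_pad > g & d_pad <= band_um - g
  h <- nrow(aqp4); w <- ncol(aqp4)
  inside <- matrix(FALSE, nrow(d_pad), ncol(d_pad))
  inside[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  frac <- sum(in_band_pad & inside) / max(sum(in_band_pad), 1L)
  if (frac < min_fraction) {
    message(sprintf(
      "vessel %d skipped: only %.0f%% of its endfoot annulus lies in the image",
      vessel$id, 100 * frac))
    return(NULL)
  }
  d_self <- d_pad[pad + seq_len(h), pad + seq_len(w)]
  d_all <- wall_distance_um(all_lumen, psz)
  endfoot_sel <- d_self > g & d_self <= band_um - g & !all_lumen
  neuro_sel <- d_all >= neuropil_range_um[1L] + g &
    d_all <= neuropil_range_um[2L] - g
  if (!any(endfoot_sel) || !any(neuro_sel)) {
    message(sprintf("vessel %d skipped: empty compartment selection", vessel$id))
    return(NULL)
  }
  ef <- mean(aqp4[endfoot_sel])
  np <- mean(aqp4[neuro_sel])
  list(pv_endfoot_if = ef, neuropil_if = np,
       n_endfoot_px = sum(endfoot_sel), n_neuropil_px = sum(neuro_sel),
       ratio = ef / np)
}

#' Radial AQP4 cross-section profile of a large vessel
#'
#' Samples the AQP4 channel along a line through the vessel center
#' perpendicular to the vessel axis, on both sides, at pixel-size steps.
#' Each side is folded about its wall crossing (distance 0 at the wall) and
#' the two sides are averaged per distance bin; in-lumen samples (of this
#' or any other vessel) are excluded. Sampling is nearest-neighbor so that
#' piecewise-constant scenes keep pure compartment levels. If neither side
#' reaches `max_dist_um`, the profile is flagged truncated and tail bins
#' are missing.
#'
#' @param aqp4 numeric matrix of the AQP4 channel.
#' @param vessel a `VesselAnnotation` of class `large`.
#' @param all_lumen logical matrix of every lumen (defaults to this
#'   vessel's).
#' @param pixel_size_um micrometers per pixel.
#' @param max_dist_um outer profiling distance (default 68 um).
#' @return a `CrossSectionProfile`: list with `profile` (data.frame
#'   `distance_um`, `mean_intensity`, `n`), `truncated`, `profile_axis`
#'   (sampling direction, unit x-y vector), `vessel_id`, `diameter_um`.
#' @export
cross_section_profile <- function(aqp4, vessel, all_lumen = NULL,
                                  pixel_size_um, max_dist_um = 68) {
  stopifnot(inherits(vessel, "VesselAnnotation"))
  if (vessel$vessel_class != "large") {
    stop("cross_section_profile expects a large-vessel annotation")
  }
  psz <- pixel_size_um
  if (is.null(all_lumen)) all_lumen <- vessel$lumen
  if (vessel$near_circular) {
    message(sprintf(
      "vessel %d: near-circular cross-section, profile axis defaults to the image x-axis",
      vessel$id))
    dir_xy <- c(1, 0)
  } else {
    # sample perpendicular to the principal axis
    dir_xy <- c(-vessel$axis_xy[2L], vessel$axis_xy[1L])
  }
  h <- nrow(aqp4); w <- ncol(aqp4)
  nbins <- ceiling(max_dist_um / psz)
  sums <- numeric(nbins); counts <- integer(nbins)
  reach <- 0
  # distance of every pixel from this vessel's wall; lumen pixels < 0
  dmap_um <- wall_distance_um(vessel$lumen, psz)
  for (side in c(1, -1)) {
    # walk outward from the center in pixel steps; samples are binned by
    # their wall distance so the two folded sides share one distance scale
    s <- 0L
    repeat {
      x <- vessel$center_px[1L] + side * s * dir_xy[1L]
      y <- vessel$center_px[2L] + side * s * dir_xy[2L]
      r <- round(y); c <- round(x)
      if (r < 1 || r > h || c < 1 || c > w) break
      dist_um <- dmap_um[r, c]
      if (dist_um > max_dist_um) break
      if (dist_um > 0 && !all_lumen[r, c]) {  # outside every lumen
        bin <- floor(dist_um / psz) + 1L
        if (bin >= 1L && bin <= nbins) {
          sums[bin] <- sums[bin] + aqp4[r, c]
          counts[bin] <- counts[bin] + 1L
          reach <- max(reach, dist_um)
        }
      }
      s <- s + 1L
    }
  }
  mean_int <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  profile <- data.frame(distance_um = (seq_len(nbins) - 0.5) * psz,
                        mean_intensity = mean_int, n = counts)
  structure(list(profile = profile, truncated = reach < max_dist_um,
                 profile_axis = dir_xy, vessel_id = vessel$id,
                 diameter_um = vessel$diameter_um),
            class = "CrossSectionProfile")
}

#' Three-compartment segmentation of a cross-section profile
#'
#' Averages profile bins into the perivascular endfoot (0-1.5 um from the
#' wall), perivascular astrocyte (1.5-20 um) and neuropil (20-68 um)
#' compartments. Intervals are half-open on the right except the outermost,
#' which includes its upper bound; means are weighted by per-bin sample
#' counts and missing bins are excluded. A compartment with no bins is
#' missing.
#'
#' @param profile a `CrossSectionProfile` (or its `profile` data.frame).
#' @param boundaries compartment boundaries in um (default `c(1.5, 20, 68)`).
#' @return a `CompartmentMeasures` list: `pv_endfoot_if`, `pv_astro_if`,
#'   `neuropil_if`, `boundaries`, `n` (bins per compartment), `vessel_id`,
#'   `diameter_um`.
#' @export
segment_profile <- function(profile, boundaries = c(1.5, 20, 68)) {
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  vessel_id <- NA_integer_; diameter_um <- NA_real_
  if (inherits(profile, "CrossSectionProfile")) {
    vessel_id <- profile$vessel_id
    diameter_um <- profile$diameter_um
    profile <- profile$profile
  }
  if (max(profile$distance_um[profile$n > 0], 0) < boundaries[1L]) {
    stop("profile does not extend to the first compartment boundary")
  }
  lims <- c(0, boundaries)
  comp_mean <- function(lo, hi, closed_right = FALSE) {
    sel <- profile$distance_um >= lo &
      (if (closed_right) profile$distance_um <= hi
       else profile$distance_um < hi) &
      profile$n > 0 & !is.na(profile$mean_intensity)
    if (!any(sel)) return(list(mean = NA_real_, n = 0L))
    wt <- profile$n[sel]
    list(mean = sum(profile$mean_intensity[sel] * wt) / sum(wt),
         n = sum(sel))
  }
  ef <- comp_mean(lims[1L], lims[2L])
  pa <- comp_mean(lims[2L], lims[3L])
  np <- comp_mean(lims[3L], lims[4L], closed_right = TRUE)
  structure(list(pv_endfoot_if = ef$mean, pv_astro_if = pa$mean,
                 neuropil_if = np$mean, boundaries = boundaries,
                 n = c(pv_endfoot = ef$n, pv_astro = pa$n, neuropil = np$n),
                 vessel_id = vessel_id, diameter_um = diameter_um),
            class = "CompartmentMeasures")
}

#' Association between compartment intensity and vessel diameter
#'
#' Ordinary least squares of a compartment intensity on vessel diameter,
#' per group, plus a group-by-diameter interaction test for a difference in
#' slopes (the aged-vs-young comparison of the perivascular astrocyte
#' trend).
#'
#' @param values compartment intensities (AU), one per vessel.
#' @param diameters vessel diameters (um).
#' @param groups group labels (factor or character), one per vessel.
#' @return list: `per_group` data.frame (`group`, `n`, `slope`,
#'   `intercept`, `r_squared`, `p_value`), `interaction_p` (NA for a single
#'   group).
#' @export
diameter_association <- function(values, diameters, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(values))
  stopifnot(length(values) == length(diameters),
            length(values) == length(groups))
  df <- data.frame(value = values, diameter = diameters,
                   group = factor(groups))
  df <- df[stats::complete.cases(df), ]
  if (stats::var(df$diameter) == 0) {
    stop("degenerate design: all diameters are equal")
  }
  tab <- table(df$group)
  if (any(tab < 3)) {
    stop(sprintf("need >= 3 vessels per group (got: %s)",
                 paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  per_group <- do.call(rbind, lapply(levels(df$group), function(g) {
    sub <- df[df$group == g, ]
    fit <- stats::lm(value ~ diameter, data = sub)
    sm <- summary(fit)
    p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2L, 4L] else NA_real_
    data.frame(group = g, n = nrow(sub),
               slope = stats::coef(fit)[[2L]],
               intercept = stats::coef(fit)[[1L]],
               r_squared = sm$r.squared, p_value = p)
  }))
  interaction_p <- NA_real_
  if (nlevels(df$group) > 1) {
    full <- stats::lm(value ~ diameter * group, data = df)
    red <- stats::lm(value ~ diameter + group, data = df)
    interaction_p <- stats::anova(red, full)[2L, "Pr(>F)"]
  }
  list(per_group = per_group, interaction_p = interaction_p)
}

#' GFP puncta areas and the large:small count ratio
#'
#' Given a GFP channel, segments puncta (connected components above
#' `detect_fraction` of the image maximum) and measures each punctum's area
#' above half its peak intensity; or accepts a vector of areas directly.
#' Counts puncta of at least 2 um^2 (`n_large`) and of at most 1 um^2
#' (`n_small`); areas strictly between 1 and 2 um^2 belong to neither
#' class. The ratio is undefined (NA, flagged) when `n_small` is 0.
#'
#' @param gfp numeric matrix of the GFP channel (or `NULL`).
#' @param areas_um2 puncta areas in um^2 (alternative to `gfp`).
#' @param pixel_size_um micrometers per pixel; required with an image.
#' @param detect_fraction detection threshold as a fraction of the image
#'   maximum (default 0.2).
#' @return a `PunctaSet` list: `areas_um2`, `n_large`, `n_small`,
#'   `ratio_large_small`, `ratio_undefined`.
#' @export
puncta_metrics <- function(gfp = NULL, areas_um2 = NULL, pixel_size_um = NULL,
                           detect_fraction = 0.2) {
  if (is.null(gfp) == is.null(areas_um2)) {
    stop("supply exactly one of `gfp` or `areas_um2`")
  }
  if (!is.null(gfp)) {
    if (is.null(pixel_size_um)) stop("pixel_size_um required with an image")
    mx <- max(gfp)
    areas_um2 <- numeric()
    if (mx > 0) {
      lab <- EBImage::bwlabel(EBImage::Image((gfp >= detect_fraction * mx) * 1))
      labm <- matrix(as.integer(lab), nrow = nrow(gfp))
      if (max(labm) > 0) {
        areas_um2 <- vapply(seq_len(max(labm)), function(i) {
          px <- gfp[labm == i]
          sum(px >= max(px) / 2) * pixel_size_um^2
        }, 0)
      }
    }
  }
  if (length(areas_um2) && any(areas_um2 <= 0)) stop("areas must be > 0")
  n_large <- sum(areas_um2 >= 2)
  n_small <- sum(areas_um2 <= 1)
  structure(list(areas_um2 = areas_um2, n_large = n_large, n_small = n_small,
                 ratio_large_small = if (n_small == 0) NA_real_ else n_large / n_small,
                 ratio_undefined = n_small == 0),
            class = "PunctaSet")
}

#' Perivascular vs fine-process GFP localization ratio
#'
#' Mean GFP intensity within the perivascular band (0 to `band_um` outside
#' any vessel wall) divided by the mean over the remaining tissue (lumens
#' excluded from both).
#'
#' @param gfp numeric matrix of the GFP channel.
#' @param lumen logical matrix of all vessel lumens (or a list of
#'   `VesselAnnotation`s whose lumens are unioned).
#' @param band_um perivascular band width (default 1.5 um).
#' @param pixel_size_um micrometers per pixel.
#' @return list: `ratio`, `band_mean`, `rest_mean`, `n_band_px`,
#'   `n_rest_px`.
#' @export
gfp_localization_ratio <- function(gfp, lumen, band_um = 1.5, pixel_size_um) {
  if (is.list(lumen) && !is.matrix(lumen)) {
    if (length(lumen) == 0L) stop("need at least one vessel")
    lumen <- Reduce(`|`, lapply(lumen, function(v) v$lumen))
  }
  if (!any(lumen)) stop("need at least one vessel")
  d <- wall_distance_um(lumen, pixel_size_um)
  band_sel <- !lumen & d > 0 & d <= band_um
  rest_sel <- !lumen & d > band_um
  if (!any(rest_sel)) stop("empty tissue remainder outside the perivascular band")
  if (!any(band_sel)) stop("empty perivascular band")
  bm <- mean(gfp[band_sel]); rm_ <- mean(gfp[rest_sel])
  list(ratio = bm / rm_, band_mean = bm, rest_mean = rm_,
       n_band_px = sum(band_sel), n_rest_px = sum(rest_sel))
}
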