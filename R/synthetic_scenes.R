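#' Vessel geometry for a synthetic scene
#'
#' @param center_px vessel center `(x, y)` in (possibly fractional) pixel
#'   coordinates, origin at the image corner.
#' @param diameter_um lumen diameter in micrometers.
#' @param shape `"tube"` (straight capillary/vessel crossing the field) or
#'   `"disk"` (penetrating vessel seen in cross-section).
#' @param orientation_deg axis direction of a tube, degrees from the image
#'   x-axis (90 = vertical). Ignored for disks.
#' @return a `vessel_geom` list.
#' @export
vessel_geom <- function(center_px, diameter_um, shape = c("tube", "disk"),
                        orientation_deg = 90) {
  shape <- match.arg(shape)
  stopifnot(length(center_px) == 2L, diameter_um > 0)
  structure(list(center_px = as.numeric(center_px),
                 diameter_um = as.numeric(diameter_um),
                 shape = shape,
                 orientation_deg = as.numeric(orientation_deg)),
            class = "vessel_geom")
}

#' Specification of a synthetic two-channel vessel scene
#'
#' Defines the generative model for an AQP4 + lectin micrograph: a neuropil
#' baseline, a bright perivascular endfoot ring of width `endfoot_band_um`
#' at each vessel wall, a diffuse perivascular-astrocyte shell out to
#' `pv_astro_extent_um` whose amplitude grows with vessel diameter at
#' `pv_astro_diameter_slope` AU/um, and a lectin channel marking lumens.
#' Intensities are arbitrary fluorescence units (AU); no absolute scale is
#' implied. Noise is Gaussian read noise plus optional Poisson shot noise.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um micrometers per pixel (default 0.42, the 2-photon
#'   sampling used for the rodent imaging).
#' @param vessels list of [vessel_geom()] objects.
#' @param endfoot_band_um endfoot ring width in micrometers (default 1.5).
#' @param endfoot_intensity,pv_astro_intensity,neuropil_intensity,lumen_intensity
#'   compartment levels in AU. `lumen_intensity` is the lectin-channel lumen
#'   level; the AQP4 channel is `aqp4_lumen_intensity` inside lumens.
#' @param aqp4_lumen_intensity AQP4 level inside lumens (default 0).
#' @param pv_astro_extent_um outer radius of the perivascular astrocyte
#'   shell, micrometers from the wall (default 20).
#' @param pv_astro_diameter_slope increase of the astrocyte-shell amplitude
#'   per micrometer of vessel diameter (AU/um, default 0).
#' @param noise_gaussian_sigma Gaussian read-noise SD in AU (default 0).
#' @param noise_poisson_scale photons per AU for Poisson shot noise; 0
#'   disables shot noise (default 0).
#' @param lipofuscin_density density of bright confound puncta (puncta/mm^2,
#'   default 0) added to the AQP4 channel.
#' @param seed mandatory RNG seed; identical spec + seed gives bit-identical
#'   scenes.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(width_px, height_px, pixel_size_um = 0.42,
                       vessels = list(),
                       endfoot_band_um = 1.5,
                       endfoot_intensity = 200,
                       pv_astro_intensity = 120,
                       neuropil_intensity = 80,
                       lumen_intensity = 500,
                       aqp4_lumen_intensity = 0,
                       pv_astro_extent_um = 20,
                       pv_astro_diameter_slope = 0,
                       noise_gaussian_sigma = 0,
                       noise_poisson_scale = 0,
                       lipofuscin_density = 0,
                       seed = 1L) {
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               pixel_size_um = pixel_size_um, vessels = vessels,
               endfoot_band_um = endfoot_band_um,
               endfoot_intensity = endfoot_intensity,
               pv_astro_intensity = pv_astro_intensity,
               neuropil_intensity = neuropil_intensity,
               lumen_intensity = lumen_intensity,
               aqp4_lumen_intensity = aqp4_lumen_intensity,
               pv_astro_extent_um = pv_astro_extent_um,
               pv_astro_diameter_slope = pv_astro_diameter_slope,
               noise_gaussian_sigma = noise_gaussian_sigma,
               noise_poisson_scale = noise_poisson_scale,
               lipofuscin_density = lipofuscin_density,
               seed = seed)
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (width_px < 1 || height_px < 1) stop("image size must be positive")
    if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
    if (endfoot_band_um <= 0) stop("endfoot_band_um must be > 0")
    for (v in c(endfoot_intensity, pv_astro_intensity, neuropil_intensity,
                lumen_intensity, aqp4_lumen_intensity)) {
      if (v < 0) stop("all intensities must be >= 0")
    }
    if (noise_gaussian_sigma < 0 || noise_poisson_scale < 0 ||
        lipofuscin_density < 0) {
      stop("noise and confound parameters must be >= 0")
    }
    if (pv_astro_extent_um < endfoot_band_um) {
      stop("pv_astro_extent_um must be >= endfoot_band_um")
    }
  })
  for (v in spec$vessels) {
    if (!inherits(v, "vessel_geom")) stop("vessels must be vessel_geom objects")
  }
  invisible(spec)
}

# Signed distance (um) of every pixel center from the wall of one vessel:
# negative inside the lumen, 0 at the wall, positive outside.
vessel_wall_distance <- function(vessel, width_px, height_px, pixel_size_um) {
  xs <- (seq_len(width_px) - 0.5) * pixel_size_um
  ys <- (seq_len(height_px) - 0.5) * pixel_size_um
  cx <- (vessel$center_px[1L]) * pixel_size_um
  cy <- (vessel$center_px[2L]) * pixel_size_um
  X <- matrix(xs, nrow = height_px, ncol = width_px, byrow = TRUE)
  Y <- matrix(ys, nrow = height_px, ncol = width_px)
  if (vessel$shape == "disk") {
    r <- sqrt((X - cx)^2 + (Y - cy)^2)
  } else {
    th <- vessel$orientation_deg * pi / 180
    # distance from the axis line through (cx, cy) with direction (cos, sin)
    r <- abs(-sin(th) * (X - cx) + cos(th) * (Y - cy))
  }
  r - vessel$diameter_um / 2
}

check_vessel_bounds <- function(vessel, width_px, height_px, pixel_size_um,
                                margin_um = 0) {
  w_um <- width_px * pixel_size_um
  h_um <- height_px * pixel_size_um
  cx <- vessel$center_px[1L] * pixel_size_um
  cy <- vessel$center_px[2L] * pixel_size_um
  rad <- vessel$diameter_um / 2 + margin_um
  if (vessel$shape == "disk") {
    ok <- cx - rad >= 0 && cx + rad <= w_um && cy - rad >= 0 && cy + rad <= h_um
  } else {
    th <- vessel$orientation_deg * pi / 180
    n <- c(-sin(th), cos(th))  # unit normal to the tube axis
    p1 <- c(cx, cy) + rad * n
    p2 <- c(cx, cy) - rad * n
    inside <- function(p) p[1L] >= 0 && p[1L] <= w_um && p[2L] >= 0 && p[2L] <= h_um
    ok <- inside(p1) && inside(p2)
  }
  if (!ok) {
    stop(sprintf(
      "vessel (center %.1f,%.1f px, diameter %.1f um) exceeds the %d x %d px image bounds",
      vessel$center_px[1L], vessel$center_px[2L], vessel$diameter_um,
      width_px, height_px))
  }
  invisible(TRUE)
}

#' Generate a synthetic AQP4 + lectin vessel scene with ground truth
#'
#' Renders the scene defined by a [scene_spec()]: per-pixel compartment
#' labels (lumen / endfoot / perivascular astrocyte / neuropil, assigned by
#' the nearest vessel wall), the AQP4 channel as piecewise-constant
#' compartment levels plus noise, and the lectin channel marking lumens.
#' The returned ground truth carries the label raster, the per-vessel true
#' diameters, and the planted compartment means, so that every downstream
#' measurement can be checked by parameter recovery.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `image` (an [image2d()] with channels `aqp4`,
#'   `lectin`) and `truth` (a `SceneGroundTruth` list: `labels` matrix coded
#'   0 = neuropil, 1 = lumen, 2 = endfoot, 3 = pv_astro; `vessels`
#'   data.frame; `planted` compartment means; `contrast`; `seed`).
#' @export
generate_vessel_scene <- function(spec) {
  validate_scene_spec(spec)
  w <- spec$width_px; h <- spec$height_px; psz <- spec$pixel_size_um
  for (v in spec$vessels) check_vessel_bounds(v, w, h, psz)

  labels <- matrix(0L, nrow = h, ncol = w)      # 0 = neuropil
  owner <- matrix(0L, nrow = h, ncol = w)       # index of the nearest vessel
  dmin <- matrix(Inf, nrow = h, ncol = w)
  for (i in seq_along(spec$vessels)) {
    d <- vessel_wall_distance(spec$vessels[[i]], w, h, psz)
    upd <- d < dmin
    dmin[upd] <- d[upd]
    owner[upd] <- i
  }
  labels[dmin <= 0] <- 1L
  labels[dmin > 0 & dmin <= spec$endfoot_band_um] <- 2L
  labels[dmin > spec$endfoot_band_um & dmin <= spec$pv_astro_extent_um] <- 3L

  aqp4 <- matrix(spec$neuropil_intensity, nrow = h, ncol = w)
  aqp4[labels == 1L] <- spec$aqp4_lumen_intensity
  aqp4[labels == 2L] <- spec$endfoot_intensity
  if (any(labels == 3L)) {
    diam <- vapply(spec$vessels, function(v) v$diameter_um, 0)
    astro_level <- spec$pv_astro_intensity +
      spec$pv_astro_diameter_slope * diam
    sel <- labels == 3L
    aqp4[sel] <- astro_level[owner[sel]]
  }
  lectin <- matrix(0.02 * spec$lumen_intensity, nrow = h, ncol = w)
  lectin[labels == 1L] <- spec$lumen_intensity

  img <- with_seed(spec$seed, {
    if (spec$lipofuscin_density > 0) {
      area_mm2 <- w * h * psz^2 * 1e-6
      n <- stats::rpois(1L, spec$lipofuscin_density * area_mm2)
      if (n > 0) {
        px <- cbind(sample.int(h, n, replace = TRUE),
                    sample.int(w, n, replace = TRUE))
        amp <- 3 * max(spec$endfoot_intensity, spec$neuropil_intensity)
        for (k in seq_len(n)) {
          rr <- max(1L, px[k, 1L] - 1L):min(h, px[k, 1L] + 1L)
          cc <- max(1L, px[k, 2L] - 1L):min(w, px[k, 2L] + 1L)
          aqp4[rr, cc] <- aqp4[rr, cc] + amp
        }
      }
    }
    add_noise <- function(m) {
      if (spec$noise_poisson_scale > 0) {
        m <- matrix(stats::rpois(length(m), m * spec$noise_poisson_scale) /
                      spec$noise_poisson_scale, nrow = nrow(m))
      }
      if (spec$noise_gaussian_sigma > 0) {
        m <- m + matrix(stats::rnorm(length(m), 0, spec$noise_gaussian_sigma),
                        nrow = nrow(m))
      }
      pmax(m, 0)
    }
    list(aqp4 = add_noise(aqp4), lectin = add_noise(lectin))
  })

  vessels_df <- if (length(spec$vessels)) {
    data.frame(
      vessel = seq_along(spec$vessels),
      center_x_px = vapply(spec$vessels, function(v) v$center_px[1L], 0),
      center_y_px = vapply(spec$vessels, function(v) v$center_px[2L], 0),
      diameter_um = vapply(spec$vessels, function(v) v$diameter_um, 0),
      shape = vapply(spec$vessels, function(v) v$shape, ""),
      orientation_deg = vapply(spec$vessels, function(v) v$orientation_deg, 0)
    )
  } else {
    data.frame(vessel = integer(), center_x_px = numeric(),
               center_y_px = numeric(), diameter_um = numeric(),
               shape = character(), orientation_deg = numeric())
  }

  truth <- list(
    labels = labels,
    vessels = vessels_df,
    planted = list(neuropil = spec$neuropil_intensity,
                   endfoot = spec$endfoot_intensity,
                   pv_astro = spec$pv_astro_intensity,
                   pv_astro_diameter_slope = spec$pv_astro_diameter_slope,
                   lumen_lectin = spec$lumen_intensity),
    contrast = spec$endfoot_intensity / spec$neuropil_intensity,
    seed = spec$seed
  )
  class(truth) <- "SceneGroundTruth"

  list(image = image2d(list(aqp4 = img$aqp4, lectin = img$lectin), psz),
       truth = truth)
}
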