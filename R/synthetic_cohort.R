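#' Generate a human-style AQP4 ROI with planted polarization contrast
#'
#' Emulates one frontal-cortex ROI from a slide-scanned AQP4 channel as the
#' dual-threshold workflow sees it: a dim slide/neuropil background, a
#' "cellular" population of astroglial fine-process texture at
#' `cellular_intensity`, and bright perivascular endfoot rings at
#' `contrast * cellular_intensity` around a handful of vessel profiles.
#' The ground truth records the label raster, the planted contrast, and the
#' planted [threshold_pair()] (midpoints between the levels) so that the
#' measured polarization ratio can be compared with the planted value.
#'
#' @param contrast planted endfoot:cellular intensity ratio (>= 1). At
#'   contrast 1 the endfoot and cellular levels coincide: the planted vessel
#'   threshold degenerates to the cellular level and the dual-threshold
#'   estimator has no class separation (see the methods vignette).
#' @param width_px,height_px ROI size in pixels (default 500).
#' @param pixel_size_um micrometers per pixel (default 0.65, slide scanner).
#' @param background,cellular_intensity intensity levels in AU.
#' @param cellular_fraction target area fraction of cellular texture.
#' @param n_vessels number of vessel profiles rendered in the ROI.
#' @param noise_sigma Gaussian noise SD in AU.
#' @param seed RNG seed.
#' @return list with `image` (an [image2d()], channel `aqp4`) and `truth`
#'   (labels coded 0 = background, 1 = cellular, 2 = endfoot, 3 = lumen;
#'   `contrast`; `thresholds`; `levels`).
#' @export
generate_human_roi <- function(contrast, width_px = 500, height_px = 500,
                               pixel_size_um = 0.65, background = 20,
                               cellular_intensity = 100,
                               cellular_fraction = 0.3, n_vessels = 8,
                               noise_sigma = 0, seed = 1L) {
  stopifnot(contrast > 0, cellular_fraction > 0, cellular_fraction < 1)
  endfoot <- contrast * cellular_intensity
  out <- with_seed(seed, {
    labels <- matrix(0L, nrow = height_px, ncol = width_px)
    # cellular fine-process texture: thresholded blurred noise field
    field <- matrix(stats::runif(width_px * height_px), nrow = height_px)
    field <- as.matrix(EBImage::gblur(EBImage::Image(field), sigma = 2))
    labels[field >= stats::quantile(field, 1 - cellular_fraction)] <- 1L
    # endfoot rings around randomly placed vessel profiles
    ring_w_px <- max(2, round(1.5 / pixel_size_um))
    placed <- matrix(NA_real_, nrow = 0, ncol = 3)  # x, y, outer radius px
    tries <- 0L
    while (nrow(placed) < n_vessels && tries < 50L * n_vessels) {
      tries <- tries + 1L
      r_lum <- stats::runif(1, 4, 12)
      r_out <- r_lum + ring_w_px
      cx <- stats::runif(1, r_out + 2, width_px - r_out - 2)
      cy <- stats::runif(1, r_out + 2, height_px - r_out - 2)
      if (nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
              placed[, 3] + r_out + 4)) {
        placed <- rbind(placed, c(cx, cy, r_out))
        X <- matrix(seq_len(width_px), nrow = height_px, ncol = width_px,
                    byrow = TRUE)
        Y <- matrix(seq_len(height_px), nrow = height_px, ncol = width_px)
        rr <- sqrt((X - cx)^2 + (Y - cy)^2)
        labels[rr <= r_lum] <- 3L
        labels[rr > r_lum & rr <= r_out] <- 2L
      }
    }
    img <- matrix(background, nrow = height_px, ncol = width_px)
    img[labels == 1L] <- cellular_intensity
    img[labels == 2L] <- endfoot
    img[labels == 3L] <- background
    if (noise_sigma > 0) {
      img <- pmax(img + matrix(stats::rnorm(length(img), 0, noise_sigma),
                               nrow = height_px), 0)
    }
    list(img = img, labels = labels)
  })
  vt <- if (endfoot > cellular_intensity) (cellular_intensity + endfoot) / 2 else endfoot
  truth <- list(labels = out$labels, contrast = contrast,
                thresholds = threshold_pair(vt,
                                            (background + cellular_intensity) / 2),
                levels = c(background = background,
                           cellular = cellular_intensity, endfoot = endfoot),
                seed = seed)
  list(image = image2d(list(aqp4 = out$img), pixel_size_um), truth = truth)
}

#' Generate a p-tau channel ROI with planted somata
#'
#' Renders `n_somata` AT8-positive soma profiles as bright disks of
#' diameter `soma_diameter_um` on a dim background, placed without overlap.
#'
#' @param n_somata number of somata to plant.
#' @param width_px,height_px ROI size in pixels.
#' @param pixel_size_um micrometers per pixel.
#' @param soma_diameter_um soma profile diameter (default 12 um).
#' @param amplitude,background intensities in AU.
#' @param noise_sigma Gaussian noise SD in AU.
#' @param seed RNG seed.
#' @return list with `image` ([image2d()], channel `ptau`) and `truth`
#'   (data.frame of planted centers in pixels).
#' @export
generate_ptau_roi <- function(n_somata, width_px = 500, height_px = 500,
                              pixel_size_um = 0.65, soma_diameter_um = 12,
                              amplitude = 200, background = 10,
                              noise_sigma = 3, seed = 1L) {
  r_px <- soma_diameter_um / 2 / pixel_size_um
  with_seed(seed, {
    img <- matrix(background, nrow = height_px, ncol = width_px)
    centers <- matrix(NA_real_, nrow = 0, ncol = 2)
    tries <- 0L
    while (nrow(centers) < n_somata && tries < 200L * max(n_somata, 1)) {
      tries <- tries + 1L
      cx <- stats::runif(1, r_px + 2, width_px - r_px - 2)
      cy <- stats::runif(1, r_px + 2, height_px - r_px - 2)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
              2 * r_px + 4)) {
        centers <- rbind(centers, c(cx, cy))
      }
    }
    if (nrow(centers) < n_somata) {
      stop("could not place all somata without overlap")
    }
    if (n_somata > 0) {
      X <- matrix(seq_len(width_px) - 0.5, nrow = height_px, ncol = width_px,
                  byrow = TRUE)
      Y <- matrix(seq_len(height_px) - 0.5, nrow = height_px, ncol = width_px)
      for (i in seq_len(n_somata)) {
        img[(X - centers[i, 1])^2 + (Y - centers[i, 2])^2 <= r_px^2] <- amplitude
      }
    }
    if (noise_sigma > 0) {
      img <- pmax(img + matrix(stats::rnorm(length(img), 0, noise_sigma),
                               nrow = height_px), 0)
    }
    truth <- if (n_somata > 0) {
      data.frame(soma = seq_len(n_somata), x_px = centers[, 1],
                 y_px = centers[, 2])
    } else {
      data.frame(soma = integer(), x_px = numeric(), y_px = numeric())
    }
    list(image = image2d(list(ptau = img), pixel_size_um), truth = truth)
  })
}

#' Specification of a synthetic subject cohort
#'
#' Defines the cohort-level generative model for the human-style analysis:
#' diagnostic (or genotype/age) groups with planted mean polarization ratio
#' and between-subject SD, a number of ROIs imaged per subject, and linear
#' links from the planted subject ratio to the clinical covariates (MMSE,
#' CDR Sum of Boxes, CERAD score, Braak stage, p-tau density). Covariate
#' links are `value = intercept + slope * ratio + N(0, sd)`, then clamped to
#' the scale range and rounded for the ordinal scores.
#'
#' @param groups data.frame with columns `label`, `n_subjects`,
#'   `mean_ratio`, `sd_ratio`.
#' @param rois_per_subject ROIs imaged per subject (default 6, as for the
#'   frontal cortical gray matter).
#' @param roi_px ROI side length in pixels.
#' @param pixel_size_um micrometers per pixel.
#' @param covariates named list of `c(intercept, slope, sd)` links; defaults
#'   emulate cognitively-driven covariates declining/rising with
#'   polarization loss.
#' @param roi_sd within-subject SD of the per-ROI realized contrast.
#' @param seed RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(groups, rois_per_subject = 6, roi_px = 500,
                        pixel_size_um = 0.65,
                        covariates = list(
                          MMSE = c(4, 12, 1.5),
                          CDR_SoB = c(17, -7.5, 1),
                          CERAD = c(5.5, -2, 0.5),
                          Braak = c(10, -3.5, 0.8),
                          ptau_density = c(90, -35, 8)),
                        roi_sd = 0, seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("label", "n_subjects", "mean_ratio", "sd_ratio") %in%
                  names(groups)))
  if (any(groups$n_subjects < 2)) {
    stop("n_subjects must be >= 2 per group for any statistical stage")
  }
  if (any(groups$sd_ratio < 0) || roi_sd < 0) stop("sd must be >= 0")
  structure(list(groups = groups, rois_per_subject = rois_per_subject,
                 roi_px = roi_px, pixel_size_um = pixel_size_um,
                 covariates = covariates, roi_sd = roi_sd, seed = seed),
            class = "cohort_spec")
}

covariate_ranges <- list(MMSE = c(0, 30), CDR_SoB = c(0, 18),
                         CERAD = c(0, 3), Braak = c(0, 6),
                         ptau_density = c(0, Inf))

#' Generate a synthetic cohort with ground truth
#'
#' Draws one planted polarization ratio per subject from the group
#' distribution, generates the linked clinical covariates, and (optionally)
#' renders `rois_per_subject` ROI images per subject via
#' [generate_human_roi()], each realizing the subject's ratio (plus
#' within-subject ROI jitter `roi_sd`).
#'
#' @param spec a [cohort_spec()].
#' @param render if `TRUE`, render ROI images; if `FALSE`, return only the
#'   ground-truth subject table (used for replicated statistical
#'   simulations where the imaging stage is validated separately).
#' @return list with `subjects` (ground-truth data.frame: `subject_id`,
#'   `group`, `ratio_true`, covariates) and `rois` (per subject, a list of
#'   `generate_human_roi()` results, or `NULL` when `render = FALSE`).
#' @export
generate_cohort <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$groups
  with_seed(spec$seed, {
    subjects <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      n <- g$n_subjects[i]
      data.frame(
        subject_id = sprintf("%s_%02d", g$label[i], seq_len(n)),
        group = g$label[i],
        ratio_true = stats::rnorm(n, g$mean_ratio[i], g$sd_ratio[i]))
    }))
    subjects$ratio_true <- pmax(subjects$ratio_true, 0.2)
    for (cv in names(spec$covariates)) {
      par <- spec$covariates[[cv]]
      val <- par[1] + par[2] * subjects$ratio_true +
        stats::rnorm(nrow(subjects), 0, par[3])
      rng <- covariate_ranges[[cv]]
      if (!is.null(rng)) val <- pmin(pmax(val, rng[1]), rng[2])
      if (cv %in% c("CERAD", "Braak", "MMSE")) val <- round(val)
      subjects[[cv]] <- val
    }
    rois <- NULL
    if (render) {
      rois <- lapply(seq_len(nrow(subjects)), function(i) {
        lapply(seq_len(spec$rois_per_subject), function(j) {
          contrast <- max(subjects$ratio_true[i] +
                            stats::rnorm(1, 0, spec$roi_sd), 0.2)
          generate_human_roi(
            contrast, width_px = spec$roi_px, height_px = spec$roi_px,
            pixel_size_um = spec$pixel_size_um,
            noise_sigma = 5,
            seed = (spec$seed * 1009L + i * 131L + j) %% .Machine$integer.max)
        })
      })
      names(rois) <- subjects$subject_id
    }
    list(subjects = subjects, rois = rois)
  })
}
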