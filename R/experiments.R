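#' Polarization-ratio recovery experiment
#'
#' Generates human-style ROIs over a grid of planted endfoot:cellular
#' contrasts and relative noise levels, measures each with the
#' dual-threshold workflow using the planted thresholds, and summarizes the
#' recovery error per grid cell. Noise is expressed relative to the
#' cellular level (100 AU). ROIs whose vessel or cellular class is empty
#' (possible when the planted contrast is 1 and the thresholds degenerate)
#' are counted as undefined and excluded from the cell mean.
#'
#' @param contrasts planted contrast grid.
#' @param sigmas_rel relative noise grid (fraction of the cellular level).
#' @param n_rois ROIs per cell.
#' @param roi_px ROI side length in pixels.
#' @param seed RNG seed.
#' @return data.frame: `contrast`, `sigma_rel`, `mean_ratio`, `rel_err`,
#'   `n_defined`, `n_undefined`.
#' @export
recover_polarization <- function(contrasts = c(1, 1.5, 2, 3),
                                 sigmas_rel = c(0, 0.05, 0.10),
                                 n_rois = 20, roi_px = 300, seed = 1L) {
  grid <- expand.grid(contrast = contrasts, sigma_rel = sigmas_rel)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    ct <- grid$contrast[i]; sg <- grid$sigma_rel[i]
    ratios <- vapply(seq_len(n_rois), function(r) {
      g <- generate_human_roi(ct, width_px = roi_px, height_px = roi_px,
                              noise_sigma = sg * 100,
                              seed = (seed * 7919L + i * 613L + r) %%
                                .Machine$integer.max)
      measure_roi_aqp4(get_channel(g$image, "aqp4"),
                       g$truth$thresholds)$polarization_ratio
    }, 0)
    ok <- !is.na(ratios)
    data.frame(contrast = ct, sigma_rel = sg,
               mean_ratio = if (any(ok)) mean(ratios[ok]) else NA_real_,
               rel_err = if (any(ok)) abs(mean(ratios[ok]) - ct) / ct else NA_real_,
               n_defined = sum(ok), n_undefined = sum(!ok))
  })
  do.call(rbind, out)
}

#' Capillary endfoot equalization experiment (syntrophin-null phenotype)
#'
#' Renders capillary scenes whose endfoot ring intensity equals the
#' neuropil level — the situation after loss of perivascular anchoring —
#' and measures the geometric endfoot:neuropil ratio through the full
#' segmentation pipeline.
#'
#' @param n_scenes number of replicate scenes.
#' @param sigma_rel relative Gaussian noise (fraction of the neuropil
#'   level, 80 AU).
#' @param seed RNG seed.
#' @return list: `mean_ratio`, `ratios`.
#' @export
snta1_equalization <- function(n_scenes = 10, sigma_rel = 0.05, seed = 1L) {
  ratios <- vapply(seq_len(n_scenes), function(s) {
    spec <- scene_spec(240, 240, vessels = list(
      vessel_geom(c(120, 120), 6, "tube", 90)),
      endfoot_intensity = 80, pv_astro_intensity = 80,
      neuropil_intensity = 80, pv_astro_extent_um = 1.6,
      noise_gaussian_sigma = sigma_rel * 80,
      seed = (seed * 131L + s) %% .Machine$integer.max)
    g <- generate_vessel_scene(spec)
    vs <- segment_vessels(g$image)
    cc <- capillary_compartments(get_channel(g$image, "aqp4"), vs[[1L]],
                                 pixel_size_um = g$image$pixel_size_um)
    cc$ratio
  }, 0)
  list(mean_ratio = mean(ratios), ratios = ratios)
}

#' Perivascular-astrocyte slope recovery experiment
#'
#' Renders one large-vessel cross-section scene per vessel with the
#' astrocyte-shell amplitude growing with diameter at the planted slope,
#' runs the full profile pipeline, and regresses the recovered astrocyte
#' compartment intensity on the recovered diameter.
#'
#' @param n_vessels number of vessels.
#' @param slope planted slope (AU/um).
#' @param diameter_range_um sampled diameter range.
#' @param noise_sigma Gaussian noise SD in AU.
#' @param seed RNG seed.
#' @return list: `slope`, `r_squared`, `per_vessel` data.frame.
#' @export
astro_slope_recovery <- function(n_vessels = 50, slope = 2,
                                 diameter_range_um = c(12, 40),
                                 noise_sigma = 0, seed = 1L) {
  diams <- with_seed(seed, stats::runif(n_vessels, diameter_range_um[1L],
                                        diameter_range_um[2L]))
  rows <- lapply(seq_len(n_vessels), function(i) {
    size <- 2L * ceiling((diams[i] / 2 + 25) / 0.42) + 40L
    spec <- scene_spec(size, size, vessels = list(
      vessel_geom(c(size / 2, size / 2), diams[i], "disk")),
      pv_astro_intensity = 120, pv_astro_diameter_slope = slope,
      noise_gaussian_sigma = noise_sigma,
      seed = (seed * 211L + i) %% .Machine$integer.max)
    g <- generate_vessel_scene(spec)
    vs <- segment_vessels(g$image)
    big <- vs[[which.max(vapply(vs, function(v) v$diameter_um, 0))]]
    pr <- suppressMessages(cross_section_profile(
      get_channel(g$image, "aqp4"), big,
      pixel_size_um = g$image$pixel_size_um))
    cm <- segment_profile(pr)
    data.frame(diameter_true = diams[i], diameter_meas = big$diameter_um,
               pv_astro_if = cm$pv_astro_if)
  })
  df <- do.call(rbind, rows)
  fit <- diameter_association(df$pv_astro_if, df$diameter_meas)
  list(slope = fit$per_group$slope, r_squared = fit$per_group$r_squared,
       per_vessel = df)
}

#' Aged-vs-young phenotype detection rates
#'
#' Replicated measurement-level cohorts (aged: endfoot reduced 30%,
#' perivascular astrocyte raised 40% on top of the diameter scaling;
#' neuropil unchanged), each analyzed with the cluster-aware mixed model.
#' Returns per-compartment rejection rates at alpha = 0.05: power for the
#' planted endfoot and astrocyte effects, type-I error for the unchanged
#' neuropil.
#'
#' @param n_rep replicate cohorts.
#' @param n_animals animals per group.
#' @param vessels_per_animal vessels per animal.
#' @param seed RNG seed.
#' @return list: `endfoot_rate`, `astro_rate`, `neuropil_rate`, `n_rep`.
#' @export
phenotype_detection_rates <- function(n_rep = 100, n_animals = 6,
                                      vessels_per_animal = 15, seed = 1L) {
  groups <- data.frame(label = c("young", "aged"), n_animals = n_animals,
                       endfoot_mul = c(1, 0.7), astro_mul = c(1, 1.4),
                       neuropil_mul = c(1, 1))
  p <- t(vapply(seq_len(n_rep), function(r) {
    d <- simulate_rodent_cohort(groups,
                                vessels_per_animal = vessels_per_animal,
                                astro_diameter_slope = 2,
                                seed = (seed * 977L + r) %% .Machine$integer.max)
    vapply(c("pv_endfoot_if", "pv_astro_if", "neuropil_if"), function(m) {
      mm <- mixed_model(d[[m]], data.frame(group = d$group), d$animal)
      mm$fixed_tests["group", "Pr(>F)"]
    }, 0)
  }, c(pv_endfoot_if = 0, pv_astro_if = 0, neuropil_if = 0)))
  list(endfoot_rate = mean(p[, "pv_endfoot_if"] < 0.05),
       astro_rate = mean(p[, "pv_astro_if"] < 0.05),
       neuropil_rate = mean(p[, "neuropil_if"] < 0.05),
       n_rep = n_rep)
}

#' Type-I calibration of the statistical layer
#'
#' Simulates null data and reports rejection rates at alpha = 0.05 for the
#' Welch t-test, the one-way ANOVA with Dunnett correction (family-wise:
#' any adjusted comparison significant), and the mixed-model fixed effect.
#'
#' @param n_t,n_anova,n_mixed simulation counts per test.
#' @param n_per_group observations per group (t-test, ANOVA).
#' @param seed RNG seed.
#' @return list of rates with the simulation counts.
#' @export
stats_type1_calibration <- function(n_t = 500, n_anova = 500, n_mixed = 200,
                                    n_per_group = 15, seed = 1L) {
  t_rate <- with_seed(seed, mean(vapply(seq_len(n_t), function(r) {
    unpaired_t(stats::rnorm(n_per_group), stats::rnorm(n_per_group))$p_value < 0.05
  }, NA)))
  anova_rate <- with_seed(seed + 1, mean(vapply(seq_len(n_anova), function(r) {
    v <- stats::rnorm(3 * n_per_group)
    g <- rep(c("CN", "MCI", "AD"), each = n_per_group)
    res <- anova_posthoc(v, g, correction = "dunnett", reference = "CN")
    any(res$comparisons$p_adj < 0.05)
  }, NA)))
  mixed_rate <- with_seed(seed + 2, mean(vapply(seq_len(n_mixed), function(r) {
    cl <- rep(sprintf("a%02d", 1:8), each = 6)
    g <- rep(rep(c("wt", "ko"), 4), each = 6)
    u <- stats::rnorm(8, 0, 1)[as.integer(factor(cl))]
    y <- u + stats::rnorm(48, 0, 1)
    mm <- mixed_model(y, data.frame(group = g), cl)
    mm$fixed_tests["group", "Pr(>F)"] < 0.05
  }, NA)))
  list(t_rate = t_rate, anova_dunnett_rate = anova_rate,
       mixed_rate = mixed_rate,
       n = c(t = n_t, anova = n_anova, mixed = n_mixed))
}

#' Empirical Welch power at a unit effect
#'
#' Power of the Welch t-test for N(0,1) vs N(delta,1) samples of size n,
#' over `n_sim` simulations; compare with the closed-form noncentral-t
#' power.
#'
#' @param n_sim simulations.
#' @param n per-group sample size.
#' @param delta true mean difference.
#' @param seed RNG seed.
#' @return empirical power (proportion of p < 0.05).
#' @export
welch_power_sim <- function(n_sim = 2000, n = 20, delta = 1, seed = 1L) {
  with_seed(seed, mean(vapply(seq_len(n_sim), function(r) {
    unpaired_t(stats::rnorm(n), stats::rnorm(n, delta))$p_value < 0.05
  }, NA)))
}

#' Mixed-model variance-component recovery
#'
#' Simulates random-intercept data (cluster SD 1.0, residual SD 0.5,
#' 12 clusters of 10 observations) and reports the median absolute
#' relative error of both recovered variance components.
#'
#' @param n_sim simulations.
#' @param cluster_sd,residual_sd planted components.
#' @param n_clusters,obs_per_cluster design size.
#' @param seed RNG seed.
#' @return list: `median_err_cluster`, `median_err_residual`.
#' @export
varcomp_recovery <- function(n_sim = 100, cluster_sd = 1.0, residual_sd = 0.5,
                             n_clusters = 12, obs_per_cluster = 10,
                             seed = 1L) {
  errs <- with_seed(seed, t(vapply(seq_len(n_sim), function(r) {
    cl <- rep(sprintf("c%02d", seq_len(n_clusters)), each = obs_per_cluster)
    u <- stats::rnorm(n_clusters, 0, cluster_sd)[as.integer(factor(cl))]
    g <- rep(rep(c("x", "y"), length.out = n_clusters), each = obs_per_cluster)
    y <- 5 + u + stats::rnorm(length(cl), 0, residual_sd)
    mm <- mixed_model(y, data.frame(group = g), cl)
    abs(mm$variance_components - c(cluster_sd, residual_sd)) /
      c(cluster_sd, residual_sd)
  }, c(cluster = 0, residual = 0))))
  list(median_err_cluster = stats::median(errs[, "cluster"]),
       median_err_residual = stats::median(errs[, "residual"]))
}

#' Tracer coverage recovery and integration identity
#'
#' End-to-end tracer experiment: planted per-region fractions rendered with
#' noise and re-measured (maximum absolute recovery error); a threshold
#' sweep checked for monotonicity; and the slice-integration identity
#' (area-weighted pooled fraction) verified on randomized slice tables.
#'
#' @param seed RNG seed.
#' @param n_configs randomized integration configurations.
#' @return list: `max_abs_err`, `monotone`, `max_integration_dev`.
#' @export
tracer_recovery_experiment <- function(seed = 1L, n_configs = 100) {
  planted <- c(cortex = 0.3, hippocampus = 0.6, striatum = 0.45,
               diencephalon = 0.15)
  ts <- tracer_spec(coverage_table(planted), noise_sigma = 5,
                    seed = seed)
  g <- generate_tracer_slices(ts)
  errs <- unlist(lapply(g$slices, function(sl) {
    tc <- tracer_coverage(sl$image, sl$masks, threshold = 50)
    vapply(names(planted), function(rn) {
      abs(tc$fraction[tc$region == rn] - planted[[rn]])
    }, 0)
  }))
  sl <- g$slices[[1L]]
  prev <- NULL; monotone <- TRUE
  for (thr in seq(5, 120, length.out = 20)) {
    fr <- tracer_coverage(sl$image, sl$masks, threshold = thr)$fraction
    if (!is.null(prev) && any(fr > prev + 1e-12)) monotone <- FALSE
    prev <- fr
  }
  dev <- with_seed(seed + 1, max(vapply(seq_len(n_configs), function(r) {
    n_sl <- sample(2:5, 1)
    tab <- data.frame(slice_id = seq_len(n_sl), region = "cortex",
                      region_area_mm2 = stats::runif(n_sl, 1, 4),
                      covered_mm2 = NA, fraction = NA, threshold = 50)
    tab$covered_mm2 <- stats::runif(n_sl, 0, 1) * tab$region_area_mm2
    tab$fraction <- tab$covered_mm2 / tab$region_area_mm2
    got <- integrate_slices(tab)$fraction
    abs(got - sum(tab$covered_mm2) / sum(tab$region_area_mm2))
  }, 0)))
  list(max_abs_err = max(errs), monotone = monotone,
       max_integration_dev = dev)
}
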