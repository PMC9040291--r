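# Shared fixture builders. Everything is generated in code; oracles here are
# deliberately independent of the package's measurement paths.

# Disk lumen mask plus an intensity image that is an exact function of the
# pixel distance-to-wall (computed directly with EBImage, not through the
# package), so profile machinery can be checked against exact step levels.
make_step_disk_scene <- function(size_px = 380, radius_px = 24,
                                 pixel_size_um = 0.42,
                                 levels = c(endfoot = 200, astro = 120,
                                            neuropil = 80),
                                 boundaries_um = c(1.5, 20)) {
  X <- matrix(seq_len(size_px), size_px, size_px, byrow = TRUE)
  Y <- matrix(seq_len(size_px), size_px, size_px)
  cx <- size_px / 2
  lum <- (X - cx)^2 + (Y - cx)^2 <= radius_px^2
  d_um <- (as.matrix(EBImage::distmap(EBImage::Image((!lum) * 1))) - 0.5) *
    pixel_size_um
  img <- matrix(levels[["neuropil"]], size_px, size_px)
  img[d_um > 0 & d_um < boundaries_um[1L]] <- levels[["endfoot"]]
  img[d_um >= boundaries_um[1L] & d_um < boundaries_um[2L]] <- levels[["astro"]]
  img[d_um <= 0] <- 0
  list(aqp4 = img, lectin = lum * 500, lumen = lum, d_um = d_um,
       pixel_size_um = pixel_size_um)
}

# Capillary-style scene: one straight tube, endfoot ring at a planted
# contrast over neuropil, no astrocyte halo.
make_capillary_scene <- function(contrast = 2, diameter_um = 6,
                                 noise_sigma = 0, seed = 1L,
                                 size_px = 240, neuropil = 80) {
  spec <- scene_spec(size_px, size_px, vessels = list(
    vessel_geom(c(size_px / 2, size_px / 2), diameter_um, "tube", 90)),
    endfoot_intensity = contrast * neuropil,
    pv_astro_intensity = neuropil, neuropil_intensity = neuropil,
    pv_astro_extent_um = 1.5000001,
    noise_gaussian_sigma = noise_sigma, seed = seed)
  generate_vessel_scene(spec)
}

# Closed-form power of the two-sided two-sample t-test (equal n, known
# sigma) via the noncentral t distribution.
welch_power_oracle <- function(delta, sigma, n, alpha = 0.05) {
  ncp <- delta / (sigma * sqrt(2 / n))
  df <- 2 * n - 2
  crit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
}
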