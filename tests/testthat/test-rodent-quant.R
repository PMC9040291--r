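test_that("vessel classification follows the 10-micron rule", {
  expect_identical(classify_vessel(8), "capillary")
  expect_identical(classify_vessel(12), "large")
  expect_identical(classify_vessel(10), "large")
  expect_error(classify_vessel(0), "positive")
  expect_error(classify_vessel(-3), "positive")
})

test_that("vessel segmentation recovers tubes with diameter and class", {
  blank <- image2d(list(lectin = matrix(0, 80, 80)), 0.42)
  expect_identical(segment_vessels(blank), list())

  g <- make_capillary_scene(diameter_um = 8, size_px = 200)
  vs <- segment_vessels(g$image)
  expect_length(vs, 1L)
  expect_lt(abs(vs[[1]]$diameter_um - 8), 0.5)
  expect_identical(vs[[1]]$vessel_class, "capillary")

  spec <- scene_spec(300, 300, vessels = list(
    vessel_geom(c(70, 150), 6, "tube", 90),
    vessel_geom(c(220, 150), 20, "tube", 90)), seed = 2)
  g2 <- generate_vessel_scene(spec)
  vs2 <- segment_vessels(g2$image)
  expect_length(vs2, 2L)
  classes <- sort(vapply(vs2, function(v) v$vessel_class, ""))
  expect_identical(classes, c("capillary", "large"))
  for (v in vs2) {
    expect_identical(v$vessel_class, classify_vessel(v$diameter_um))
  }
})

test_that("capillary endfoot:neuropil ratio recovers planted contrasts", {
  for (contrast in c(1, 2, 4)) {
    for (sigma_rel in c(0, 0.05, 0.10)) {
      ratios <- vapply(1:6, function(s) {
        g <- make_capillary_scene(contrast, noise_sigma = sigma_rel * 80,
                                  seed = 100 * contrast + s)
        vs <- segment_vessels(g$image)
        cc <- capillary_compartments(get_channel(g$image, "aqp4"), vs[[1]],
                                     pixel_size_um = g$image$pixel_size_um)
        cc$ratio
      }, 0)
      expect_lt(abs(mean(ratios) - contrast) / contrast, 0.10,
                label = sprintf("contrast %g sigma %g: mean ratio %.3f",
                                contrast, sigma_rel, mean(ratios)))
    }
  }
})

test_that("a vessel whose annulus mostly leaves the image is skipped", {
  lectin <- matrix(0, 120, 120)
  lectin[1:6, 1:6] <- 500  # corner lumen
  img <- image2d(list(lectin = lectin, aqp4 = matrix(80, 120, 120)), 0.42)
  vs <- segment_vessels(img)
  expect_length(vs, 1L)
  expect_message(
    res <- capillary_compartments(get_channel(img, "aqp4"), vs[[1]],
                                  pixel_size_um = 0.42),
    "skipped")
  expect_null(res)
})

test_that("cross-section profiles fold symmetrically and respect steps", {
  sc <- make_step_disk_scene()
  img <- image2d(list(aqp4 = sc$aqp4, lectin = sc$lectin), sc$pixel_size_um)
  vs <- segment_vessels(img)
  expect_identical(vs[[1]]$vessel_class, "large")
  pr <- suppressMessages(cross_section_profile(sc$aqp4, vs[[1]],
                                               pixel_size_um = sc$pixel_size_um))
  ok <- pr$profile$n > 0
  # every sampled bin carries a pure step level
  expect_true(all(pr$profile$mean_intensity[ok] %in% c(200, 120, 80)))
  # mirror the scene: the folded profile is unchanged
  img_f <- sc$aqp4[, rev(seq_len(ncol(sc$aqp4)))]
  lect_f <- sc$lectin[, rev(seq_len(ncol(sc$lectin)))]
  vs_f <- segment_vessels(image2d(list(lectin = lect_f), sc$pixel_size_um))
  pr_f <- suppressMessages(cross_section_profile(img_f, vs_f[[1]],
                                                 pixel_size_um = sc$pixel_size_um))
  expect_equal(pr_f$profile$mean_intensity, pr$profile$mean_intensity)
})

test_that("line-profile binning agrees with a per-pixel distance-transform oracle", {
  # smooth radial scene: intensity declines linearly with wall distance
  sc <- make_step_disk_scene(size_px = 420, radius_px = 30)
  img <- 200 - 1.5 * pmax(sc$d_um, 0)
  img[sc$lumen] <- 0
  vs <- segment_vessels(image2d(list(lectin = sc$lectin), sc$pixel_size_um))
  pr <- suppressMessages(cross_section_profile(img, vs[[1]],
                                               pixel_size_um = sc$pixel_size_um))
  # oracle: average every tissue pixel by its distance-transform bin
  psz <- sc$pixel_size_um
  bins <- floor(sc$d_um / psz) + 1L
  sel <- sc$d_um > 0 & bins <= nrow(pr$profile)
  oracle <- tapply(img[sel], bins[sel], mean)
  got <- pr$profile$mean_intensity[as.integer(names(oracle))]
  ok <- !is.na(got)
  expect_gt(sum(ok), 100)
  expect_true(all(abs(got[ok] - oracle[ok]) / oracle[ok] < 0.01))
})

test_that("profile segmentation averages the three compartments", {
  flat <- data.frame(distance_um = seq(0.21, 67.9, by = 0.42))
  flat$mean_intensity <- 100
  flat$n <- 2L
  cm <- segment_profile(flat)
  expect_identical(c(cm$pv_endfoot_if, cm$pv_astro_if, cm$neuropil_if),
                   c(100, 100, 100))
  step <- flat
  step$mean_intensity <- ifelse(step$distance_um < 1.5, 200,
                                ifelse(step$distance_um < 20, 120, 80))
  cm2 <- segment_profile(step)
  expect_identical(c(cm2$pv_endfoot_if, cm2$pv_astro_if, cm2$neuropil_if),
                   c(200, 120, 80))
  # bins within 68 um belong to exactly one compartment
  expect_identical(sum(cm2$n), nrow(step))
  short <- flat[flat$distance_um < 1, ]
  expect_error(segment_profile(short), "does not extend")
  tail_missing <- step
  tail_missing$n[tail_missing$distance_um > 20] <- 0L
  cm3 <- segment_profile(tail_missing)
  expect_true(is.na(cm3$neuropil_if))
})

test_that("diameter association fits exact slopes and detects differences", {
  set.seed(5)
  diam <- runif(30, 12, 40)
  res <- diameter_association(2 * diam + 10, diam)
  expect_equal(res$per_group$slope, 2, tolerance = 1e-10)
  expect_equal(res$per_group$r_squared, 1, tolerance = 1e-10)
  expect_error(diameter_association(rnorm(10), rep(5, 10)), "degenerate")
  expect_error(diameter_association(rnorm(4), c(1, 2, 3, 4),
                                    c("a", "a", "a", "b")), ">= 3")

  # planted slope difference 0.5 vs 2.0 is detected in most replicates
  hits <- vapply(seq_len(200), function(r) {
    set.seed(3000 + r)
    d1 <- runif(50, 12, 40); d2 <- runif(50, 12, 40)
    v1 <- 0.5 * d1 + rnorm(50, 0, 8)
    v2 <- 2.0 * d2 + rnorm(50, 0, 8)
    da <- diameter_association(c(v1, v2), c(d1, d2),
                               rep(c("young", "aged"), each = 50))
    da$interaction_p < 0.05
  }, NA)
  expect_gte(mean(hits), 0.90)

  # shuffled diameters carry no association
  r2 <- vapply(seq_len(50), function(r) {
    set.seed(4000 + r)
    d <- runif(40, 12, 40)
    v <- 2 * d + rnorm(40, 0, 5)
    diameter_association(v, sample(d))$per_group$r_squared
  }, 0)
  expect_lt(mean(r2), 0.08)
})

test_that("puncta classes and ratio follow the 2 / 1 um^2 gates", {
  pm <- puncta_metrics(areas_um2 = c(0.5, 0.8, 2.5, 3.0))
  expect_identical(pm$n_small, 2L)
  expect_identical(pm$n_large, 2L)
  expect_identical(pm$ratio_large_small, 1)
  gap <- puncta_metrics(areas_um2 = 1.5)
  expect_identical(gap$n_small + gap$n_large, 0L)
  expect_true(gap$ratio_undefined)
  expect_error(puncta_metrics(areas_um2 = c(1, -2)), "> 0")
})

test_that("segmented puncta areas recover planted areas within 15%", {
  set.seed(77)
  areas <- runif(50, 0.3, 4.0)
  g <- generate_puncta_field(areas, pixel_size_um = 0.1, seed = 13)
  pm <- puncta_metrics(gfp = get_channel(g$image, "gfp"), pixel_size_um = 0.1)
  expect_identical(length(pm$areas_um2), 50L)
  got <- sort(pm$areas_um2)
  want <- sort(areas)
  expect_true(all(abs(got - want) / want < 0.15))
  # gate counts can differ by the odd punctum rendered within quantization
  # of the 1 / 2 um^2 class boundaries
  truth_ratio <- sum(areas >= 2) / sum(areas <= 1)
  expect_lt(abs(pm$ratio_large_small - truth_ratio) / truth_ratio, 0.10)
})

test_that("GFP localization ratio matches a brute-force pixel scan", {
  g <- make_capillary_scene(diameter_um = 6, size_px = 160)
  lumen <- g$truth$labels == 1L
  psz <- g$image$pixel_size_um
  uniform <- matrix(50, 160, 160)
  expect_identical(gfp_localization_ratio(uniform, lumen,
                                          pixel_size_um = psz)$ratio, 1)
  # confine GFP to the endfoot band; oracle via explicit distance scan
  d <- (as.matrix(EBImage::distmap(EBImage::Image((!lumen) * 1))) - 0.5) * psz
  band <- !lumen & d > 0 & d <= 1.5
  gfp <- matrix(5, 160, 160); gfp[band] <- 120
  res <- gfp_localization_ratio(gfp, lumen, pixel_size_um = psz)
  oracle <- mean(gfp[band]) / mean(gfp[!lumen & !band])
  expect_equal(res$ratio, oracle, tolerance = 1e-12)
  expect_gt(res$ratio, 1)
  inverted <- matrix(120, 160, 160); inverted[band] <- 5
  expect_lt(gfp_localization_ratio(inverted, lumen,
                                   pixel_size_um = psz)$ratio, 1)
  expect_error(gfp_localization_ratio(uniform, matrix(FALSE, 3, 3),
                                      pixel_size_um = psz), "at least one")
})

test_that("all-vessel and per-animal pooling agree on balanced designs", {
  d <- simulate_rodent_cohort(
    data.frame(label = c("young", "aged"), n_animals = 4, endfoot_mul = c(1, 0.7),
               astro_mul = 1, neuropil_mul = 1), vessels_per_animal = 10,
    seed = 11)
  pools <- pool_vessel_measures(d, "pv_endfoot_if")
  expect_equal(pools$grand_means$all_vessels, pools$grand_means$per_animal,
               tolerance = 1e-12)
  expect_identical(nrow(pools$per_animal), 8L)
})
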