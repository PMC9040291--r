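test_that("identical spec and seed give bit-identical scenes", {
  spec <- scene_spec(120, 120, vessels = list(vessel_geom(c(60, 60), 8)),
                     noise_gaussian_sigma = 10, noise_poisson_scale = 0.5,
                     seed = 42)
  a <- generate_vessel_scene(spec)
  b <- generate_vessel_scene(spec)
  expect_identical(a$image$channels$aqp4, b$image$channels$aqp4)
  expect_identical(a$image$channels$lectin, b$image$channels$lectin)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("noiseless scenes reproduce planted compartment means exactly", {
  spec <- scene_spec(200, 200, vessels = list(vessel_geom(c(100, 100), 8)),
                     endfoot_intensity = 200, neuropil_intensity = 100,
                     pv_astro_intensity = 150, seed = 1)
  g <- generate_vessel_scene(spec)
  aqp4 <- get_channel(g$image, "aqp4")
  expect_identical(mean(aqp4[g$truth$labels == 2L]), 200)
  expect_identical(mean(aqp4[g$truth$labels == 0L]), 100)
  expect_identical(mean(aqp4[g$truth$labels == 3L]), 150)
  expect_identical(g$truth$contrast, 2)
})

test_that("noisy compartment means recover planted values via the label raster", {
  spec <- scene_spec(500, 500, vessels = list(vessel_geom(c(250, 250), 12)),
                     endfoot_intensity = 200, neuropil_intensity = 100,
                     noise_gaussian_sigma = 10, seed = 7)
  g <- generate_vessel_scene(spec)
  aqp4 <- get_channel(g$image, "aqp4")
  for (lab in c(0L, 2L, 3L)) {
    planted <- c(`0` = 100, `2` = 200, `3` = 120)[[as.character(lab)]]
    expect_lt(abs(mean(aqp4[g$truth$labels == lab]) - planted), 2)
  }
})

test_that("labels partition the raster and vessels out of bounds are rejected", {
  spec <- scene_spec(150, 150, vessels = list(
    vessel_geom(c(40, 40), 6), vessel_geom(c(110, 100), 20, "disk")), seed = 3)
  g <- generate_vessel_scene(spec)
  expect_true(all(g$truth$labels %in% 0:3))
  expect_identical(length(g$truth$labels), 150L * 150L)
  bad <- scene_spec(100, 100, vessels = list(vessel_geom(c(5, 50), 30, "disk")),
                    seed = 1)
  expect_error(generate_vessel_scene(bad), "exceeds")
})

test_that("cohort generator: degenerate variance and group-mean recovery", {
  spec0 <- cohort_spec(data.frame(label = c("CN", "AD"), n_subjects = 4,
                                  mean_ratio = c(2, 1.5), sd_ratio = 0),
                       seed = 5)
  c0 <- generate_cohort(spec0, render = FALSE)
  expect_identical(c0$subjects$ratio_true,
                   rep(c(2, 1.5), each = 4))
  expect_error(
    cohort_spec(data.frame(label = "CN", n_subjects = 1, mean_ratio = 2,
                           sd_ratio = 0.1)),
    "n_subjects")

  # planted CN 2.0 vs AD 1.5, measured through the dual-threshold pipeline
  spec <- cohort_spec(data.frame(label = c("CN", "AD"), n_subjects = 12,
                                 mean_ratio = c(2, 1.5), sd_ratio = 0.2),
                      rois_per_subject = 3, roi_px = 300, seed = 9)
  ch <- generate_cohort(spec, render = TRUE)
  measured <- vapply(ch$subjects$subject_id, function(sid) {
    vals <- vapply(ch$rois[[sid]], function(roi) {
      measure_roi_aqp4(get_channel(roi$image, "aqp4"),
                       roi$truth$thresholds)$polarization_ratio
    }, 0)
    aggregate_subject(vals)$mean
  }, 0)
  for (g in c("CN", "AD")) {
    sel <- ch$subjects$group == g
    expect_lt(abs(mean(measured[sel]) - mean(ch$subjects$ratio_true[sel])),
              0.1)
  }
})

test_that("cohorts with identical group means give a calibrated ANOVA", {
  spec <- cohort_spec(data.frame(label = c("CN", "MCI", "AD"),
                                 n_subjects = 12, mean_ratio = 2,
                                 sd_ratio = 0.2), seed = 0)
  p <- vapply(seq_len(200), function(r) {
    spec$seed <- 1000L + r
    ch <- generate_cohort(spec, render = FALSE)
    summary(stats::aov(ratio_true ~ group, data = ch$subjects))[[1]][
      1, "Pr(>F)"]
  }, 0)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("tracer slices realize planted fractions up to pixel quantization", {
  ts <- tracer_spec(coverage_table(c(cortex = 0.5, hippocampus = 0,
                                     striatum = 1, diencephalon = 0.25)),
                    seed = 3)
  g <- generate_tracer_slices(ts)
  expect_true(all(abs(g$truth$planted - g$truth$realized) < 0.01))
  sl <- g$slices[[1]]
  tr <- get_channel(sl$image, "tracer")
  expect_identical(sum(tr[sl$masks$hippocampus] > 0), 0L)
  expect_error(
    tracer_spec(coverage_table(c(cortex = 1.2, hippocampus = 0,
                                 striatum = 0, diencephalon = 0))),
    "\\[0, 1\\]")
})

test_that("puncta render the requested above-half-maximum areas", {
  # one 1 um^2 punctum at 0.1 um/px: ~100 px above half max
  g1 <- generate_puncta_field(1.0, pixel_size_um = 0.1, seed = 2)
  gfp <- get_channel(g1$image, "gfp")
  expect_lt(abs(sum(gfp >= max(gfp) / 2) - 100), 8)
  # empty request: blank image
  g0 <- generate_puncta_field(numeric(), pixel_size_um = 0.1, seed = 2)
  expect_identical(max(get_channel(g0$image, "gfp")), 0)
  expect_identical(nrow(g0$truth), 0L)
  # impossible packing errors out
  expect_error(
    generate_puncta_field(rep(2, 50), pixel_size_um = 0.1, width_px = 60,
                          height_px = 60, seed = 1, max_retries = 20),
    "without overlap")
})
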