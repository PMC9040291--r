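test_that("dual-threshold measurement matches exact arithmetic", {
  v <- c(rep(200, 50), rep(100, 500), rep(10, 449450))
  roi <- matrix(v, nrow = 500)
  m <- measure_roi_aqp4(roi, threshold_pair(150, 50))
  expect_identical(m$polarization_ratio, 2)
  expect_identical(m$cellular_area_coverage, 550 / 450000)
  expect_identical(m$mean_if, mean(v))
  expect_false(m$undefined)
})

test_that("empty threshold classes flag the measure undefined", {
  roi <- matrix(5, 50, 50)
  m <- measure_roi_aqp4(roi, threshold_pair(150, 50))
  expect_true(m$undefined)
  expect_true(is.na(m$polarization_ratio))
})

test_that("class means equal a brute-force pixel scan", {
  set.seed(21)
  roi <- matrix(runif(5000, 0, 300), 50, 100)
  th <- threshold_pair(220, 90)
  m <- measure_roi_aqp4(roi, th)
  vessel_px <- c()
  cellular_px <- c()
  for (i in seq_len(nrow(roi))) for (j in seq_len(ncol(roi))) {
    x <- roi[i, j]
    if (x >= 220) vessel_px <- c(vessel_px, x)
    else if (x >= 90) cellular_px <- c(cellular_px, x)
  }
  expect_identical(m$polarization_ratio, mean(vessel_px) / mean(cellular_px))
  expect_identical(m$cellular_area_coverage,
                   (length(vessel_px) + length(cellular_px)) / length(roi))
})

test_that("polarization ratio is scale-invariant and endfoot-monotone", {
  set.seed(31)
  for (rep in 1:5) {
    roi <- matrix(runif(2500, 0, 300), 50, 50)
    th <- threshold_pair(250, 100)
    m1 <- measure_roi_aqp4(roi, th)
    k <- runif(1, 0.5, 4)
    m2 <- measure_roi_aqp4(roi * k, threshold_pair(250 * k, 100 * k))
    expect_equal(m2$polarization_ratio, m1$polarization_ratio,
                 tolerance = 1e-12)
    expect_equal(m2$cellular_area_coverage, m1$cellular_area_coverage)
    # raising only vessel-class pixels strictly raises the ratio
    roi_up <- roi
    roi_up[roi >= 250] <- roi_up[roi >= 250] + 20
    expect_gt(measure_roi_aqp4(roi_up, th)$polarization_ratio,
              m1$polarization_ratio)
  }
})

test_that("coverage stays in [0,1] and hits 1 iff all pixels pass", {
  roi <- matrix(c(100, 200, 300, 400), 2, 2)
  expect_identical(measure_roi_aqp4(roi, threshold_pair(350, 50))$
                     cellular_area_coverage, 1)
  expect_lt(measure_roi_aqp4(roi, threshold_pair(350, 150))$
              cellular_area_coverage, 1)
})

test_that("automatic thresholds separate a two-level image", {
  set.seed(41)
  v <- sample(c(rep(100, 900), rep(200, 100)))
  roi <- matrix(v, 25, 40)
  th <- auto_thresholds(roi)
  expect_lte(th$cellular_threshold, 100)
  expect_lt(th$cellular_threshold, th$vessel_threshold)
  expect_lte(th$vessel_threshold, 200)
  expect_gt(th$vessel_threshold, 100)
  expect_error(auto_thresholds(matrix(7, 10, 10)), "zero intensity variance")
})

test_that("auto thresholds put nearly all ground-truth endfoot pixels in the vessel class", {
  g <- generate_human_roi(3, width_px = 300, height_px = 300,
                          cellular_fraction = 0.35, noise_sigma = 5, seed = 6)
  aqp4 <- get_channel(g$image, "aqp4")
  th <- auto_thresholds(aqp4, vessel_quantile = 0.97)
  ef <- aqp4[g$truth$labels == 2L]
  expect_gt(mean(ef >= th$vessel_threshold), 0.95)
})

test_that("ROI placement is feasible, non-overlapping and seeded", {
  img <- matrix(0, 4000, 6000)
  rois <- place_rois(img, c(rep("gray", 6), rep("white", 6)), roi_px = 1000,
                     seed = 3)
  expect_identical(nrow(rois), 12L)
  expect_identical(sum(rois$label == "gray"), 6L)
  expect_identical(sum(rois$label == "white"), 6L)
  # non-overlap: no two ROIs share any grid cell
  key <- paste(rois$x, rois$y)
  expect_identical(anyDuplicated(key), 0L)
  expect_identical(place_rois(img, rep("gray", 6), seed = 3),
                   place_rois(img, rep("gray", 6), seed = 3))
  expect_error(place_rois(matrix(0, 900, 900), "gray", roi_px = 1000),
               "at most 0")
})

test_that("p-tau density arithmetic and blob recovery", {
  d <- ptau_density(count = 12, width_px = 1000, height_px = 1000,
                    pixel_size_um = 0.65)
  expect_equal(d$area_mm2, 0.4225)
  expect_equal(d$density_per_mm2, 12 / 0.4225, tolerance = 1e-12)
  expect_identical(ptau_density(count = 0, width_px = 100, height_px = 100,
                                pixel_size_um = 0.65)$density_per_mm2, 0)
  expect_error(ptau_density(count = 5, width_px = 10, height_px = 10,
                            pixel_size_um = NULL), "required")
  g <- generate_ptau_roi(25, seed = 8)
  d2 <- ptau_density(roi_image = get_channel(g$image, "ptau"),
                     pixel_size_um = 0.65)
  expect_lte(abs(d2$count - 25), 1)
})

test_that("subject aggregation averages valid ROIs and reports exclusions", {
  expect_identical(aggregate_subject(c(2.0, 2.2, 1.8, 2.0, 2.1, 1.9))$mean, 2)
  ag <- aggregate_subject(c(2.0, 2.2, 1.8, 2.0, 2.1, 9.9),
                          excluded = c(rep(FALSE, 5), TRUE))
  expect_equal(ag$mean, mean(c(2.0, 2.2, 1.8, 2.0, 2.1)))
  expect_identical(ag$n_used, 5L)
  bad <- aggregate_subject(c(NA_real_, NA_real_))
  expect_true(is.na(bad$mean))
  expect_match(bad$reason, "no valid ROI")
})
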