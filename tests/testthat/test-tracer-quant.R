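test_that("coverage arithmetic is exact on constructed slices", {
  masks <- make_region_masks(100, 100)
  tr <- matrix(0, 100, 100)
  idx <- which(masks$cortex, arr.ind = TRUE)
  half <- idx[seq_len(floor(nrow(idx) / 2)), ]
  tr[half] <- 100
  tc <- tracer_coverage(tr, masks, threshold = 50, pixel_size_um = 10)
  expect_equal(tc$fraction[tc$region == "cortex"],
               floor(nrow(idx) / 2) / nrow(idx))
  blank <- tracer_coverage(matrix(0, 100, 100), masks, threshold = 50,
                           pixel_size_um = 10)
  expect_true(all(blank$fraction == 0))
})

test_that("generated fronts are recovered within 0.02 despite noise", {
  planted <- c(cortex = 0.3, hippocampus = 0.6, striatum = 0.45,
               diencephalon = 0.15)
  ts <- tracer_spec(coverage_table(planted), noise_sigma = 5, seed = 17)
  g <- generate_tracer_slices(ts)
  for (sl in g$slices) {
    tc <- tracer_coverage(sl$image, sl$masks, threshold = 50)
    for (rn in names(planted)) {
      expect_lt(abs(tc$fraction[tc$region == rn] - planted[[rn]]), 0.02)
    }
  }
})

test_that("raising the threshold never raises any coverage", {
  ts <- tracer_spec(coverage_table(c(cortex = 0.4, hippocampus = 0.7,
                                     striatum = 0.2, diencephalon = 0.5)),
                    noise_sigma = 8, seed = 23)
  g <- generate_tracer_slices(ts)
  sl <- g$slices[[3]]
  prev <- NULL
  for (thr in seq(10, 120, length.out = 20)) {
    fr <- tracer_coverage(sl$image, sl$masks, threshold = thr)$fraction
    if (!is.null(prev)) expect_true(all(fr <= prev + 1e-12))
    prev <- fr
  }
})

test_that("subregion coverage never exceeds the whole-slice coverage", {
  ts <- tracer_spec(coverage_table(c(cortex = 0.8, hippocampus = 0.1,
                                     striatum = 0.6, diencephalon = 0.3)),
                    noise_sigma = 3, seed = 5)
  g <- generate_tracer_slices(ts)
  tc <- tracer_coverage(g$slices[[1]]$image, g$slices[[1]]$masks,
                        threshold = 50)
  whole_cov <- tc$covered_mm2[tc$region == "whole"]
  expect_lte(sum(tc$covered_mm2[tc$region != "whole"]), whole_cov + 1e-12)
  expect_true(all(tc$fraction >= 0 & tc$fraction <= 1))
})

test_that("region masks are pairwise disjoint subsets of the whole", {
  for (mode in c("influx", "efflux")) {
    masks <- make_region_masks(150, 120, mode)
    sub <- masks[setdiff(names(masks), "whole")]
    overlap <- Reduce(`+`, lapply(sub, function(m) m * 1))
    expect_lte(max(overlap), 1)
    for (m in sub) expect_true(all(masks$whole[m]))
  }
  eff <- make_region_masks(150, 120, "efflux")
  expect_true(all(c("hippocampus_ipsi", "hippocampus_contra") %in% names(eff)))
})

test_that("slice integration is the area-weighted pooled fraction", {
  mk <- function(slice, region, area, covered) {
    data.frame(slice_id = slice, region = region, region_area_mm2 = area,
               covered_mm2 = covered, fraction = covered / area,
               threshold = 50)
  }
  five <- do.call(rbind, lapply(1:5, function(s) mk(s, "cortex", 2, 0.8)))
  expect_equal(integrate_slices(five)$fraction, 0.4)
  two <- rbind(mk(1, "cortex", 2, 0.4), mk(2, "cortex", 2, 1.2))
  expect_equal(integrate_slices(two)$fraction, 0.4)

  # dropping an out-of-focus slice matches brute force over the remainder
  set.seed(9)
  all5 <- do.call(rbind, lapply(1:5, function(s) {
    mk(s, "hippocampus", runif(1, 1, 3), runif(1, 0, 1))
  }))
  kept <- all5[all5$slice_id != 3, ]
  res <- suppressMessages(integrate_slices(kept, expected_slices = 1:5))
  expect_equal(res$fraction, sum(kept$covered_mm2) / sum(kept$region_area_mm2),
               tolerance = 1e-15)
  expect_identical(res$n_slices, 4L)
})
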