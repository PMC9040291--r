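#!/usr/bin/env Rscript
# Stage 1 — synthetic data with planted ground truth.
#
# Generates one example of each synthetic input the later stages consume:
# a capillary field and a large-vessel cross-section (AQP4 + lectin), a
# human-style cohort, a tracer slice series, and a puncta field. Writes the
# ground-truth tables under results/; the rasters themselves are
# regenerated on demand from the recorded specs (everything is a pure
# function of spec + seed).

suppressMessages(library(perivaq))
dir.create("results", showWarnings = FALSE)

scene <- generate_vessel_scene(scene_spec(
  400, 400, vessels = list(vessel_geom(c(120, 200), 6, "tube", 90),
                           vessel_geom(c(280, 200), 22, "disk")),
  pv_astro_diameter_slope = 2, noise_gaussian_sigma = 4, seed = 11))
lab <- table(factor(scene$truth$labels, 0:3,
                    c("neuropil", "lumen", "endfoot", "pv_astro")))
write.csv(data.frame(compartment = names(lab), n_px = as.integer(lab)),
          "results/01_scene_label_counts.csv", row.names = FALSE)
write.csv(scene$truth$vessels, "results/01_scene_vessels.csv",
          row.names = FALSE)
cat("scene: ", nrow(scene$truth$vessels), "vessels;",
    "planted endfoot:neuropil contrast", scene$truth$contrast, "\n")

cohort <- generate_cohort(cohort_spec(
  data.frame(label = c("CN", "MCI", "AD"), n_subjects = c(10, 8, 10),
             mean_ratio = c(2.0, 1.8, 1.5), sd_ratio = 0.2),
  rois_per_subject = 4, roi_px = 300, seed = 12), render = FALSE)
write.csv(cohort$subjects, "results/01_cohort_ground_truth.csv",
          row.names = FALSE)
cat("cohort:", nrow(cohort$subjects), "subjects across",
    length(unique(cohort$subjects$group)), "groups\n")

tr <- generate_tracer_slices(tracer_spec(
  coverage_table(c(cortex = 0.45, hippocampus = 0.55, striatum = 0.4,
                   diencephalon = 0.35)), noise_sigma = 5, seed = 13))
write.csv(tr$truth, "results/01_tracer_ground_truth.csv", row.names = FALSE)
cat("tracer: ", length(tr$slices), "slices, bregma",
    paste(vapply(tr$slices, `[[`, 0, "bregma_mm"), collapse = ", "), "mm\n")

pf <- generate_puncta_field(runif(40, 0.3, 4), pixel_size_um = 0.1, seed = 14)
write.csv(pf$truth, "results/01_puncta_ground_truth.csv", row.names = FALSE)
cat("puncta:", nrow(pf$truth), "planted puncta\n")
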