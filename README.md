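# perivaq

Quantification of perivascular aquaporin-4 (AQP4) localization in
multi-channel fluorescence micrographs, with a planted-ground-truth
synthetic generator that makes every measurement stage testable by
parameter recovery.

AQP4 normally concentrates at the perivascular astrocyte endfeet that
ensheath brain vessels; loss of this polarization accompanies aging and
Alzheimer's disease and impairs glymphatic CSF–interstitial fluid
exchange. `perivaq` is aimed at imaging labs quantifying that biology:
it implements the human post-mortem dual-threshold workflow, rodent
capillary and large-vessel radial profiling, CSF tracer coverage
integration, GFP puncta classification, and the accompanying statistics.

## What it computes

* **Polarization ratio** (human ROIs): with a vessel threshold `v` and a
  cellular threshold `c < v`,
  `ratio = mean{I : I ≥ v} / mean{I : c ≤ I < v}`, plus mean intensity,
  cellular area coverage `|{I ≥ c}|/N`, and AT8 p-tau somata per mm².
* **Radial compartments** (rodent): vessels segmented from the lectin
  channel; capillaries (< 10 µm) measured as endfoot (0–1.5 µm from the
  wall) vs neuropil annuli; large vessels profiled perpendicular to
  their axis, folded at the wall, and segmented into perivascular
  endfoot (0–1.5 µm), perivascular astrocyte (1.5–20 µm) and neuropil
  (20–68 µm) compartments; compartment–diameter regressions with
  slope-difference tests.
* **Tracer coverage**: thresholded area fraction per region mask,
  integrated across coronal slices as Σcovered/Σarea (influx set 1, 0,
  −1.5, −2.5, −3.5 mm to bregma; efflux set 2.5, 1.5, 0, −1, −2 mm).
* **Puncta**: above-half-maximum areas; large (≥ 2 µm²) : small
  (≤ 1 µm²) count ratio.
* **Statistics**: ANOVA with Dunnett/Tukey/Sidak post hocs, random-
  intercept mixed models (REML, Satterthwaite) for vessels nested in
  animals, Welch t-tests, and regression with partial-regression output.

The synthetic module (`generate_vessel_scene()`, `generate_cohort()`,
`generate_tracer_slices()`, `generate_puncta_field()`, ...) renders all of
these inputs with known ground truth, which is how the package validates
itself.

## Worked example

```r
library(perivaq)

# a 240x240 px capillary field at 0.42 um/px: endfoot ring planted at
# twice the neuropil level, 5% Gaussian noise
spec <- scene_spec(240, 240,
                   vessels = list(vessel_geom(c(120, 120), 6, "tube", 90)),
                   endfoot_intensity = 160, neuropil_intensity = 80,
                   pv_astro_intensity = 80, pv_astro_extent_um = 1.6,
                   noise_gaussian_sigma = 4, seed = 7)
scene <- generate_vessel_scene(spec)

vessels <- segment_vessels(scene$image)
vessels[[1]]$diameter_um
#> [1] 5.46
vessels[[1]]$vessel_class
#> [1] "capillary"

capillary_compartments(get_channel(scene$image, "aqp4"), vessels[[1]],
                       pixel_size_um = 0.42)$ratio
#> [1] 1.99879
```

The segmented capillary recovers the planted 6 µm diameter to about one
pixel (0.42 µm) under noise, and the planted endfoot:neuropil contrast of
2.0 to three decimal places (the ground truth is in `scene$truth`).

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `05_statistics.R`): synthetic cohorts, the human
dual-threshold analysis with covariate regressions, rodent profile and
diameter-association recovery, wild-type vs knockout tracer coverage,
and statistical calibration. Each script prints what it found and writes
its tables under `results/`.

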