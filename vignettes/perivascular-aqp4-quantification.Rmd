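---
title: "Quantifying perivascular AQP4 localization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular AQP4 localization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivaq)
```

## The scientific problem

Aquaporin-4 (AQP4) is the astroglial water channel that normally
concentrates at perivascular endfeet — the astrocyte process terminals
ensheathing brain blood vessels. Loss of this *polarization* (AQP4
redistributing from endfeet into non-perivascular fine processes) is a
feature of brain aging and of Alzheimer's disease, and it impairs
glymphatic cerebrospinal fluid–interstitial fluid exchange. `perivaq`
implements the image-quantification operators used to measure this
biology in fluorescence micrographs, together with the statistical layer
that compares groups, and — crucially — a synthetic-micrograph generator
with planted ground truth so that every measurement stage is validated by
parameter recovery rather than by eye.

## The measurement models

### Dual-threshold polarization ratio (human sections)

Post-mortem human sections carry too much autofluorescence and lipofuscin
for fine line-based analysis, so quantification is threshold-based at ROI
level. Two intensity thresholds are applied to the AQP4 channel of each
ROI: a **vessel threshold** $v$ isolating the bright vessel-edge/endfoot
signal, and a lower **cellular threshold** $c$ capturing astroglial fine
processes. Writing $I_p$ for pixel intensities, the package computes

* mean unthresholded intensity $\overline{I}$,
* cellular area coverage $=|\{p : I_p \ge c\}| / N$ (a superset that
  includes the vessel class — the second threshold extends the first),
* polarization ratio
  $= \operatorname{mean}\{I_p : I_p \ge v\} \;/\;
     \operatorname{mean}\{I_p : c \le I_p < v\}$.

The cellular class excludes vessel-class pixels (half-open band):
including them in the denominator would bias the ratio toward 1, since the
ratio is meant to contrast endfoot signal against non-endfoot cellular
signal. Undefined ratios (an empty class) propagate as missing values and
are never imputed. ROI placement follows the frontal-cortex layout (6 gray
+ 6 white matter ROIs of 1000×1000 px per section); per-subject values are
the arithmetic mean over the available ROIs after exclusions (out-of-focus
images are dropped, typically 1–2 per dataset). AT8-positive p-tau somata
are counted per ROI and converted to counts/mm² by the pixel size.

The reference workflow chose both thresholds manually and blinded, and
their values are unreported; `auto_thresholds()` therefore offers a
reproducible default (vessel = 99.5th, cellular = 90th intensity
percentile, type-1 quantiles so thresholds are attained pixel values) and
every function accepts a manual `threshold_pair()`. A related reading
ambiguity — whether the recorded "mean value of this threshold" denotes
the mean of in-band pixels or the threshold value itself — is resolved
here as the mean of in-band pixels.

### Radial compartment profiling (rodent vessels)

Rodent vessels are segmented from the endothelial lectin channel (Otsu
threshold, morphological closing, connected components). Diameter is the
inscribed-disk width from the distance transform, `(2·max − 1)` pixels
for elongated lumens; near-circular cross-sections use the
area-equivalent diameter instead, which is insensitive to the sub-pixel
offset between the lumen center and the pixel grid. Vessels under 10 µm
are capillaries, all others (including exactly 10 µm, a convention for
determinism) are large vessels.

* **Capillaries**: mean AQP4 in the endfoot annulus (0–1.5 µm outside the
  wall) versus a neuropil reference annulus 5–15 µm from *any* wall. The
  1.5 µm capillary band matches the large-vessel endfoot compartment; the
  5–15 µm reference is a package choice (unstated in the source
  protocols) that stays local while avoiding endfoot contamination, and
  both are configurable. Annuli are eroded by one pixel at each radial
  edge so wall-quantization pixels do not dilute the compartment means; a
  vessel whose annulus is less than half inside the image is skipped and
  logged.
* **Large vessels**: intensity is sampled along a line through the vessel
  center perpendicular to the principal axis (for near-circular sections
  the sampling direction defaults to the image x-axis, with a logged
  note), folded about the wall, and averaged per distance bin of one
  pixel. Each sample is binned by the vessel's own wall-distance
  transform, so the two folded sides share one distance scale and
  piecewise-constant scenes reproduce their levels exactly. Lumen samples
  (of any vessel) are excluded; distances are measured outward from the
  wall, never from the vessel center. Profiles are segmented into
  perivascular endfoot (0–1.5 µm), perivascular astrocyte (1.5–20 µm) and
  neuropil (20–68 µm, upper bound inclusive) compartments, weighting by
  per-bin sample counts; truncated profiles keep missing tail bins and a
  flag.

Compartment–diameter associations are ordinary least squares per group
with a group-by-diameter interaction test for slope differences. Nested
designs (vessels within animals) are reported both as all-vessel pools
and as per-animal means; the two grand means coincide exactly for
balanced designs.

### Tracer coverage and puncta

CSF tracer influx (intracisternal) and interstitial efflux
(intraparenchymal) are quantified as thresholded area coverage per region
mask — one uniform threshold per experiment, applied to every animal and
slice — and integrated across the standard coronal sets (influx: 1, 0,
−1.5, −2.5, −3.5 mm to bregma; efflux: 2.5, 1.5, 0, −1, −2 mm) as
$\sum \text{covered area} / \sum \text{region area}$. Area-weighted
integration (rather than a mean of fractions) is robust to unequal region
areas per slice and matches integrating densities across remaining
sections when slices are excluded. Region masks are inputs drawn once per
atlas level; the efflux mode splits them at the midline into
ipsilateral/contralateral halves.

GFP puncta are measured in 2-D as above-half-maximum areas of segmented
blobs and classified as large (≥ 2 µm²) or small (≤ 1 µm²); areas in
(1, 2) µm² belong to neither class, and the large:small ratio is
undefined (never 0/0-coerced) when no small puncta exist. Perivascular
GFP localization is the mean within 1.5 µm of any wall over the mean of
the remaining tissue, lumens excluded.

### Statistics

The statistical layer mirrors the source analyses: one- and two-way
ANOVA with Dunnett (vs a reference group), Tukey (all pairs) or Sidak
corrections; linear mixed models with a per-animal random intercept
(REML, Satterthwaite denominator degrees of freedom — the standard
treatment for unbalanced nested imaging data) with Sidak post hocs;
Welch's t-test by default (no equal-variance assumption is stated in the
source protocols); and OLS with partial-regression output, whose slope
equals the multiple-regression coefficient exactly (Frisch–Waugh).
Missing values are dropped listwise with logged counts. Degenerate inputs
follow explicit conventions: two constant equal samples give t = 0,
p = 1; zero within-group variance with distinct means yields collapsed
(near-zero) p-values rather than an error.

## The synthetic generator

The generator renders what the measurement operators assume: a neuropil
baseline, an endfoot ring of configurable width (default 1.5 µm) at each
vessel wall, a diffuse perivascular-astrocyte shell out to 20 µm whose
amplitude grows with vessel diameter at a configurable slope, a lectin
channel marking lumens, Gaussian read noise plus optional Poisson shot
noise, and (off by default) sparse bright lipofuscin-like puncta.
Vessels are straight tubes or disks — curvature and network topology are
deliberately out of scope, sufficient to exercise every measurement
operator. Pixel size defaults to 0.42 µm (the 2-photon sampling of the
rodent imaging). Compartment levels are piecewise constant, so noiseless
scenes reproduce planted means exactly and recovery error shrinks as
1/√(pixel count). Absolute intensity scales are arbitrary units
throughout: the source imaging reports none, and every measured quantity
is a ratio, fraction, count or within-experiment contrast.

Cohort-level generators plant group structure: per-subject polarization
ratios drawn from group distributions (with linear links plus noise to
MMSE, CDR Sum of Boxes, CERAD, Braak and p-tau density covariates,
clamped/rounded to their scales), per-vessel compartment intensities with
per-animal random intercepts, tracer fronts filling each region to a
planted fraction (contiguous advance, ±1 pixel-column quantization,
exponential decay of length 10 µm beyond the front), and Gaussian puncta
whose above-half-maximum area equals the requested area by construction
(σ = √(area / (2π ln 2))). All generators take mandatory seeds and
restore the caller's RNG state; identical spec + seed is bit-identical.

What the generator does **not** emulate: real endfoot texture and
astrocyte morphology, depth-dependent attenuation, optics beyond
pixelation, staining batch effects, lipofuscin spectral overlap, or
vascular curvature. Passing recovery tests therefore demonstrates that
the measurement operators are unbiased and calibrated *for data obeying
their geometric assumptions* — not that any particular biological image
is measured without bias.

## Validation design and problem sizes

Validation is layered. Image-level recovery (polarization grid at
contrasts 1–3 and noise 0–10%, 20 ROIs of 300×300 px per cell; capillary
contrast grid; 50-vessel astrocyte-slope experiment; tracer fronts) is
run at small n where rendering is cheap. Replicated statistical
calibration (100 phenotype cohorts of 6 animals × 15 vessels per group;
500/500/200 null simulations for t/ANOVA/mixed tests; 2000-simulation
power checks; 100 variance-component fits at 12 clusters × 10) runs at
the measurement level through the same generative model, because the
quantity under test there is the statistical layer, not the renderer.
These sizes are the package's validation choices and are encoded in the
acceptance suite and `scripts/acceptance.R`.

## Numerical choices and edge conventions

* Distances from a wall are `(distance-transform − ½) × pixel size`,
  centering the estimate on the analytic wall; lumen pixels are negative
  and excluded from every compartment.
* Threshold classes use half-open intervals `[c, v)`; coverage uses the
  closed lower bound.
* A planted contrast of exactly 1 makes the dual-threshold estimator
  degenerate: with the endfoot and cellular levels coincident no
  threshold can separate the classes, so at zero noise the ratio is
  undefined (reported as missing), and under noise pure
  truncation-selection biases the ratio above 1 (≈ +8% at 5% noise).
  This is a property of the estimator itself; the geometric
  capillary endfoot:neuropil ratio does not share it, which is why the
  syntrophin-null equalization check uses the geometric route.
* Mixed models on data with near-zero cluster variance hit the REML
  boundary ("singular fit" notes); estimates then coincide with OLS, as
  asserted in the tests.
* Tie-break: a diameter of exactly 10 µm is a large vessel.

## Known limitations

2-D only (the source's 3-D puncta rendering is reimplemented as 2-D
above-half-maximum areas); no artery/vein discrimination; no atlas
registration (region masks are inputs); no stain normalization across
batches; thresholds are per-experiment constants, not per-image
adaptations. The printed quantitative results of the motivating human and
animal studies derive from unreleased tissue images and are not
reproducible at desk scale; the package's claims are therefore recovery
and calibration claims against planted ground truth.
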