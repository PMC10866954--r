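---
title: "Quantifying microvascular networks: models, parameters and validation"
author: "mvnquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microvascular networks: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvnquant)
```

# The problem

Self-assembled microvascular networks (MVNs) grown from retinal endothelial
cells, pericytes and astrocytes in microfluidic fibrin-gel channels are an
in-vitro model of the inner blood-retinal barrier. Under diabetic culture
conditions (high glucose plus TNF-α and IL-6) these networks display the
hallmarks of non-proliferative diabetic retinopathy: vascular regression,
pericyte dropout, loss of pericyte coverage, accumulation of *ghost
vessels* (collagen-IV basement-membrane sleeves that have lost their
endothelium) and increased tracer permeability. mvnquant implements the
image-quantification side of that assay — from multi-channel confocal
stacks to per-condition statistics — together with a synthetic scene
generator whose ground truth encodes the known condition effects, so that
every stage of the pipeline can be validated by parameter recovery without
any raw imaging data.

# 2D MIP morphometry

All projection metrics run on maximum-intensity projections (MIPs) of the
calibrated stack. Preprocessing is fixed and shared by all markers:
intensities are clipped to [0, 20000], divided by the clip value and
median-smoothed with a 3 px radius. Marker regions then come from common
fractional thresholds — 0.25 for the endothelium (UEA I), 0.40 for
pericytes (PDGFRβ), astrocytes (S100b) and the basement membrane (COL IV),
the latter after an additional 10 px median. We interpret the "common
threshold" as a fraction of the clipped display range; this reproduces the
clip + fractional-threshold convention of high-content-screening software.

Derived metrics:

* **Pericyte coverage** — the pericyte region's overlap with the EC
  region dilated by a 5 µm outer border, reported both as area (µm²) and
  as a fraction of vascular area. Dilation uses the Euclidean distance
  transform in physical units, so a border is exactly a physical distance
  rather than a pixel count (this matters on anisotropic or non-unit
  grids).
* **Ghost-vessel fraction** — (ECM area − EC∩ECM area) / ECM area,
  clamped to [0, 1] against rounding noise.
* **Nuclei** — Gaussian smoothing (σ = 2 px), global Otsu threshold, hole
  filling, distance-transform watershed, then removal of objects below
  20 µm². The smoothing/threshold/split chain is the simplest standard
  pipeline for round DAPI objects; every constant is an exposed argument.
* **Nuclei-to-region assignment** — a nucleus counts for a marker when
  its mask touches the marker region dilated by an outer border of 3 µm
  (EC), 2 µm (pericyte), 2 µm (astrocyte) or 3 µm (ECM). Assignment is
  deliberately non-exclusive: the four selections are defined
  independently, so one nucleus may count for several markers.
* **Apoptosis co-localization** — apoptotic nuclei (reporter overlap of
  at least half the nucleus at a 0.40 threshold) are assigned by the same
  border rule; viability is 1 − apoptotic/total.

# 3D stack analysis

The volumetric pipeline mirrors a two-step segmentation strategy:
classical thresholding first, an optional learned refinement second.

1. **Denoising.** In-plane Gaussian smoothing followed by slice-wise
   background subtraction. The background is estimated per z-slice by a
   grayscale opening with a separable running-min/running-max box window
   (radius 50 px by default). A box opening is used instead of a true
   rolling sphere: it is exact O(n), behaves identically on the flat and
   ramped backgrounds that matter here, and is the same morphological
   estimator our oracle tests use. Background subtraction is slice-wise
   because the z-spacing (5 µm) makes a 3D structuring element physically
   ill-posed.
2. **Multi-Otsu, 3 classes.** An exhaustive two-threshold Otsu search on a
   256-bin histogram. The top class is foreground — markers are bright on
   dark. A constant image has no histogram structure and raises a
   degenerate-histogram error rather than guessing.
3. **Object segmentation.** Closing then opening with a radius of one
   in-plane pixel *in physical units*; using physical rather than voxel
   units keeps single-slice objects alive under 5 µm z-steps. Fused
   objects are split by a seeded watershed on the (anisotropy-aware)
   Euclidean distance transform. Seeds are local maxima of the lightly
   smoothed distance map with a 3-in-plane-pixel minimum separation and
   deterministic raster-order tie-breaks; regions whose saddle distance
   reaches 70% of the weaker peak are re-merged, which removes the
   spurious splits that z-discretization plateaus otherwise cause while
   leaving thin-neck fusions split.
4. **Random-walker vasculature.** Voxels above the upper multi-Otsu cut
   seed the vessel label, voxels below the lower cut seed the background,
   and the remaining voxels are assigned by random-walker label
   propagation: the probability that a walker on the intensity-weighted
   6-neighbour graph (Gaussian weights, β = 130 on intensities normalized
   to [0, 1]) reaches a vessel seed first, obtained by solving one sparse
   SPD linear system; probability ≥ 0.5 joins the vessel. If only one
   seed class exists the whole unlabeled set follows it, matching the
   degenerate limits (everything bright → everything vessel).
5. **Vessel geometry.** The mean lumen diameter is estimated from the
   interior distance transform: for a cylinder of radius r the mean
   interior distance is r/3, so d = 6·mean(EDT) − 3·(in-plane voxel),
   the last term correcting the half-voxel offset of a discrete boundary.
   The skeleton length is then V/(π(d/2)²) — the area-equivalent
   cylinder. We chose the EDT route over topological thinning because it
   is exact on the cylinder oracle, stable on noisy masks, and needs no
   3D skeletonization dependency.
6. **Pixel classifier.** A seeded random forest (ranger) on per-voxel
   features — raw intensity plus Gaussian-smoothed intensity, gradient
   magnitude and Laplacian at σ ∈ {1, 2, 4} px — trained on
   thresholding-derived (or corrected) masks, balanced and subsampled to
   20000 voxels per class. It is an optional stage; the pipeline runs
   without it. Interactive mask correction is out of scope, so tests use
   generator truth masks as the "corrected" input.
7. **Proximity.** Objects and the vessel mask are each dilated by 3
   voxels independently in x, y and z (cubic structuring element); the
   intersection volume indicates contact. Surface distances sample the
   surface at exposed voxel-face centers (6-connectivity) in physical
   coordinates — the surface sits at the voxel interface, so touching
   masks measure distance 0 and a 4 µm face gap measures exactly 4 µm —
   and query nearest neighbours through a uniform spatial hash, the same
   role a k-d tree plays.

# Perfusion and permeability

The apparent permeability coefficient uses the cylindrical-lumen
convention

$$ P = \frac{\bar I_t(t_2) - \bar I_t(t_1)}{\bar I_v(t_1) - I_{bg}}
      \cdot \frac{1}{t_2 - t_1} \cdot \frac{\bar d}{4} $$

with the mean extravascular intensity $\bar I_t$ (outside the vessel
mask), the mean intravascular intensity $\bar I_v$, the background
$I_{bg}$ estimated from the first frame outside the 10 px-dilated mask,
times in seconds and the mean lumen diameter $\bar d$ in cm; defaults are
t₁ = 5 min and t₂ = 15 min of a 0/5/10/15 min series. A negative
extravascular increase clamps to P = 0 with a flag. The forward simulator
uses the identical linear model, which makes noise-free recovery exact by
construction — that is intentional: the estimator's correctness is
checked by closed-form inversion, and its robustness separately under the
stochastic noise model. The geometry factor is isolated so the
volume-to-surface variant (V/S from a segmented 3D mask instead of d/4)
can be swapped in; both are provided. Perfusability is the
tracer-positive percentage of the vessel-mask area at a 0.25 fractional
threshold, mirroring the endothelial threshold.

# The synthetic scene generator

The generator is first-class, tested code: it defines the study
conditions every recovery test runs under.

**Geometry.** A planar-biased vessel tree grows on a jittered random walk
(edge lengths 40–90 µm, log-normal radii with median 12 µm clipped to
5–45 µm, consistent with the 10–50 µm calibres such networks show) until
the 2D capsule footprint reaches the preset's vascular area fraction; the
final edge is length-bisected onto the target. Ghost vessels arise by
de-lumenizing whole edges (leaf-first, to keep the remaining lumen
connected) and, for fine control, splitting one edge so only its distal
portion loses endothelium. The basement-membrane channel renders at the
same capsule radius as the vessel — in a MIP a thin sleeve projects to
essentially the tube footprint — so a zero-ghost preset genuinely has an
empty ghost mask. Pericyte bodies (spheres, 5–8 µm) attach at random
azimuths on the vessel wall until the coverage fraction is met, with the
final body radius bisected onto the target; a 15% pool of detached
pericytes models free/dropped-out cells. Astrocytes scatter through the
gel. Each cell body carries one nucleus; nuclei are kept laterally
separated (≥ 12 µm in x-y) so the MIP nucleus count equals the 3D truth
count — real cells spread through the gel rather than stacking, and this
keeps 2D counting honest. Apoptotic nuclei are Bernoulli draws per cell
type.

**Realization tolerance.** Rendered scenes must realize the preset's
vascular, coverage and ghost fractions within ±5% relative; the generator
re-attempts with adjusted internal targets up to 20 times and fails
loudly otherwise. Measured realizations are stored in the scene
(`realizedFractions()`), so tests compare against what was actually
built.

**Noise model.** signal → Poisson(scale·signal)/scale + N(0, sd) + linear
background ramp, the standard shot/read/shading decomposition for
fluorescence data. Defaults: sd = 400 (2% of the display range),
poisson scale 0.01 (≈8% relative shot noise at peak), ramp to 5% of the
range across x. All three are zero-able for oracle tests, and noise-off
scenes render the truth masks exactly.

**Presets.** Only relative changes between conditions are
published, so the absolute baselines are free generator parameters chosen
once: vascular area fraction 0.30, coverage fraction 0.60, ghost fraction
0.25 at control D7. The presets then encode the printed effects: control
vascular area falls to 70% by D14 and stabilizes; diabetic networks
regress to 30% of the D7 control by D28; coverage drops 3-fold; the ghost
fraction rises 1.6-fold from D7 to diabetic D28 and is 1.3-fold above
control at D28 (control D28 ghost = 0.40/1.3 ≈ 0.31); baseline
permeability is 1×10⁻⁷ cm/s and 4.7-fold higher under TNF-α. diabetic_D14
sits at the log-midpoint of the D7 and D28 values, reflecting that the
major diabetic changes develop between D14 and D28. Apoptotic fractions
are 0.03 (control) and 0.12 (diabetic), keeping viability above ~95% and
~85% respectively. Presets are immutable once registered.

**Coverage is reported per vascular area.** The preset coverage
parameter, and the recovery target, is coverage area divided by vascular
area. Under the diabetic presets the raw coverage *area* falls ~10-fold
(coverage fraction 3-fold × vascular area 3.3-fold); the published 3-fold
coverage effect refers to coverage relative to the remaining vascular
compartment, so that is the quantity the pipeline reports alongside the
raw area.

**What the generator does not emulate.** Real stacks show out-of-focus
haze, anisotropic PSF blur, vessel taper and lumen hollowness, staining
heterogeneity, device autofluorescence and registration error between
magnifications. Passing recovery tests therefore demonstrates that the
pipeline's measurement logic is unbiased under controlled degradation —
not that it is robust to every real-world artifact; the thresholds would
need recalibration against real acquisitions.

# Statistics

Group comparisons use one-way ANOVA followed by all pairwise comparisons
on the pooled ANOVA error with Šidák adjustment
(p′ = 1 − (1 − p)^m), the same convention as common prism-style
analyses. With two groups the adjustment is the identity. A 1000-rep
null simulation keeps the empirical type-I error of the report inside
[3%, 7%] at α = 0.05. ROIs within a channel are treated as technical
replicates and reported per ROI; the pipeline also carries the
device/condition labels needed to aggregate at channel level, since
published panels mix both granularities.

# Problem sizes and determinism

The default scene grid is 512 × 256 × 40 voxels at 0.6 × 0.6 × 5 µm — a
20× field with a z-range scaled for desk-scale runtimes; anisotropy is
kept deliberately because several 3D operations (morphology, watershed,
surface extraction) are only correct if they respect it. Unit tests use
smaller grids (≈ 160 × 96 × 12) with proportionally smaller vessel radii
(median 8 µm); parameter-recovery checks of the printed effect sizes run
at the default grid with 5 seeds per condition. All randomness flows
through explicit seeds into an isolated RNG scope, so scenes, classifier
fits and pipeline tables are bit-reproducible; re-running a pipeline
config reproduces its CSV exactly.

# Known limitations

* Ghost-vessel recovery carries a small positive bias (~2–4% relative)
  from the 10 px ECM median filter; it cancels almost fully in the
  condition ratios the package reports.
* The permeability estimator shares its forward model with the
  simulator; systematic model error (e.g. non-cylindrical lumens) is not
  detectable from synthetic data alone — the V/S variant exists for
  exactly that comparison on real masks.
* OME-TIFF metadata is not parsed; calibration comes from the YAML
  sidecar, and stacks without calibration are refused.
* On very small grids the diabetic presets leave only one or two vessel
  segments; coverage granularity then limits how precisely a preset can
  be realized, which is why small-grid tests prefer the control presets.
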