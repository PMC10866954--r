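# mvnquant

Quantification of self-assembled microvascular networks (MVNs) from
multi-channel 3D fluorescence stacks, with a ground-truth synthetic scene
generator for end-to-end validation.

MVNs grown from retinal endothelial cells, pericytes and astrocytes in
microfluidic gel channels model the inner blood–retinal barrier; under
diabetic culture conditions they reproduce hallmarks of early diabetic
retinopathy. Quantifying those hallmarks from confocal stacks requires a
chain of image-analysis steps whose biases are hard to audit on real data
alone. mvnquant implements the full chain and pairs it with a seeded
simulator whose scenes have known truth, so every metric can be checked by
parameter recovery.

## What it measures

**2D (maximum-intensity projections).** Marker regions by common
fractional thresholds after clipping to [0, 20000] and 3 px median
smoothing (endothelium 0.25; pericyte, astrocyte and basement membrane
0.40, the latter after a 10 px median); nuclei by Gaussian–Otsu–watershed
segmentation; nuclei-to-region assignment with physical outer borders
(3/2/2/3 µm); pericyte coverage as the pericyte area overlapping the 5 µm
dilated endothelial region; the ghost-vessel fraction

```
F_ghost = area(ECM \ EC) / area(ECM)
```

(the avascular share of the COL IV area); apoptosis co-localization and
viability.

**3D.** Denoising (Gaussian + slice-wise background opening), 3-class
multi-Otsu segmentation with morphological cleanup and distance-transform
watershed splitting, random-walker vascular segmentation seeded by the
multi-Otsu cuts, an optional random-forest pixel-classifier refinement,
and proximity metrics (3 px dilation overlap volumes, nearest
surface-to-surface distances).

**Permeability.** The apparent permeability coefficient from a tracer
time-lapse (cylindrical-lumen convention):

```
P_app = (Ī_t(t2) − Ī_t(t1)) / (Ī_v(t1) − I_bg) · 1/(t2−t1) · d̄/4   [cm/s]
```

plus perfusability (tracer-positive % of the vessel area).

**Statistics.** One-way ANOVA with Šidák-adjusted pairwise comparisons,
normalization to a control group, and a YAML-configured pipeline that
writes per-ROI CSV tables and a JSON run manifest.

## Worked example

```r
library(mvnquant)

# a synthetic diabetic-condition scene with known ground truth
sc <- renderScene("diabetic_D28", seed = 1, dims = c(192, 96, 14),
                  radiusMedian = 8, radiusRange = c(4, 16))
realizedFractions(sc)
#> vascular_area_fraction      coverage_fraction         ghost_fraction
#>             0.09065755             0.20047876             0.40406562

m <- quantifyMip(sc)
round(m[, c("vascular_area", "coverage_fraction", "ghost_fraction",
            "nuclei_total", "viability")], 3)
#>   vascular_area coverage_fraction ghost_fraction nuclei_total viability
#> 1        597.24             0.187            0.4            6         1
```

The scene realizes the preset's targets: vascular area fraction 0.091 —
this preset regresses to 30% of the 0.30 control baseline — coverage
fraction 0.200, ghost fraction 0.404. The measurement pipeline then
recovers them from the rendered, noisy channels: the 597 µm² vascular
area over this 115 × 58 µm field is an area fraction of 597/6636 ≈ 0.090,
and the measured coverage (0.187) and ghost fraction (0.400) sit within a
few percent of the realized truth. Six nuclei are segmented, matching the
generator's truth table; none of the six drew an apoptotic flag at the
diabetic 12% rate, so viability is 1.0 on this small field.

Permeability, on the same geometry:

```r
ps  <- simulatePerfusion(sc)                      # preset leak 1e-7 cm/s
est <- estimatePermeability(ps)                   # t = 5 and 15 min
pApp(est)
#> [1] 1.007436e-07
```

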