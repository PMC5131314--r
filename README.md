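# folliculometry

Quantitative morphometry of ovarian follicles in 3D light-sheet (SPIM)
image stacks of cleared ovary tissue.

Light-sheet imaging of chemically cleared ovaries captures whole follicles
in 3D: the bright thecal wall, the dark delamination gap left by clearing,
the granulosa lining, the dark antrum, and the cumulus-oophorus complex
(COC) attached to the inner wall. Because the entire follicle is in the
stack, size can be measured volumetrically instead of with the two-caliper
histology convention, and wall thickness becomes a distribution around the
equator rather than a single number. This package is for imaging groups and
reproductive-biology labs who need that measurement chain as tested,
scriptable code rather than manual ROI work.

## What it computes

For each segmented follicle:

* **Volume** `V` = voxel count × voxel volume (mm³), and the **equivalent
  diameter** `d = (6V/π)^(1/3)` (µm) for comparison with diameter-based
  literature.
* **Equatorial plane**: the z-plane of maximal cross-section area; all 2D
  quantities are measured there.
* **Asymmetry**: major/minor axis ratio (≥ 1) of the second-moment ellipse
  of the equatorial cross-section, computed in physical coordinates so
  anisotropic voxels (default 16 × 4 × 4 µm) cannot bias it.
* **Thecal wall thickness**: for every pixel on the outer edge of the theca
  in the equatorial plane, the shortest distance to the inner edge — a full
  distribution (n ≈ 100–2,000 samples per follicle) with mean, sd and
  quartiles.
* **COC diameter**: equivalent-circle diameter at the COC's middle plane.
* **Stage**: primary (< 100 µm), antral (100–700 µm, closed interval) or
  Graafian (> 700 µm) from the equivalent diameter.
* The **two-orthogonal-caliper estimate** used in histology, included so
  its asymmetry-dependent bias can be quantified against the volumetric
  diameter.

Cohort level: per-stage volume statistics (`mean [Q1–Q3]`), a saturating
oocyte-vs-follicle growth curve `o = a·d/(b+d)` with adjusted R² against a
validation set, and inverse log-volume regressions of asymmetry and wall
thickness.

Because cleared-ovary SPIM stacks are rarely shareable, the package also
ships a **synthetic ovary phantom generator** (`phantom_spec()`,
`build_phantom()`): ovoid follicle shells with delamination gap, granulosa,
lumen and wall-attached COCs, blood-vessel tubes, primordial egg nests, a
light-sheet imaging model (axial blur growing from an 11 µm waist to 60 µm
at 3 mm off-axis, 6 µm lateral FWHM, shot + read noise) and a
voxel-accurate ground-truth manifest. Every quantitative claim in the test
suite is validated against phantom ground truth.

## Worked example

Generate the reference ten-follicle phantom (primary through Graafian,
74 µm–1.25 mm), measure it blind, and compare with the manifest:

```r
library(folliculometry)

spec <- cohort_phantom_spec(seed = 42)
res  <- build_phantom(spec)          # image_stack + ground truth, ~1.5 min
out  <- measure_stack(res$stack)     # segment + measure, ~2.5 min
out$labels
#> <label_volume> 150 x 520 x 520 voxels, 10 labels (10 follicle, 0 vessel)

out$summary$formatted
#> [1] "0.00028 [0.00025-0.00032] mm^3"  # primary  (n = 2)
#> [2] "0.038 [0.0056-0.051] mm^3"       # antral   (n = 5)
#> [3] "0.61 [0.4-0.77] mm^3"            # Graafian (n = 3)

head(out$measurements[order(out$measurements$equivalent_diameter_um),
     c("equivalent_diameter_um", "asymmetry", "thickness_mean_um",
       "coc_diameter_um", "stage")], 4)
#>   equivalent_diameter_um asymmetry thickness_mean_um coc_diameter_um   stage
#>                    74.36     1.000                NA              NA primary
#>                    87.30     1.097                NA              NA primary
#>                   149.62     1.107             29.43              NA  antral
#>                   220.26     1.072             46.08              NA  antral

ev <- evaluate_recovery(out$measurements, res$truth, measured_labels = out$labels)
str(ev$summary[c("n_matched", "max_volume_rel_err", "stage_accuracy",
                 "min_dice", "coc_recall")])
#> $ n_matched         : int 10
#> $ max_volume_rel_err: num 0.0154
#> $ stage_accuracy    : num 1
#> $ min_dice          : num 0.986
#> $ coc_recall        : num 1
```

All ten follicles are recovered with ≤ 1.6% volume error, perfect staging,
Dice ≥ 0.986 against the voxel truth, and every COC ≥ 40 µm found with
≤ 7% diameter error — under the default blur and noise model.

Real stacks enter the same way: `read_stack("stack.tiff")` (multi-page
16-bit TIFF + `{"spacing_um": [dz, dy, dx]}` sidecar, or an explicit
`spacing =`), optionally with manually drawn labels via
`measure_stack(stack, labels = "labels.tiff")`. `reslice()` and
`max_intensity_projection()` provide the standard volumetric views. A thin
CLI (`inst/cli/folliculometry.R`) exposes `simulate`, `measure` and
`evaluate` for shell pipelines.

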