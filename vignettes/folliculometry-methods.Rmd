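---
title: "Folliculometry from light-sheet stacks: models, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folliculometry from light-sheet stacks: models, phantoms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Selective plane illumination microscopy (SPIM) of chemically cleared ovary
tissue produces 3D image stacks in which whole ovarian follicles are visible
end to end: the bright thecal wall, a dark delamination band where clearing
detaches the granulosa from the theca, the granulosa lining, the dark
fluid-filled antrum, and — in many antral and Graafian follicles — a bright
cumulus-oophorus complex (COC) attached to the inner wall. Because the whole
follicle is imaged, size can be measured volumetrically rather than with the
two-caliper convention of histology, and wall thickness can be measured as a
full distribution around the equator rather than a single number.

This package implements that measurement chain: stack I/O with physical
voxel spacing, follicle segmentation, per-follicle morphometry, development
staging, and cohort statistics — plus a synthetic ovary phantom generator
with voxel-accurate ground truth, which is what every quantitative claim in
the test suite is validated against.

## Conventions

* Axis order is `(z, y, x)` with z the acquisition (sample-translation)
  axis; a voxel `(i, j, k)` (1-based) has its physical centre at
  `((i-0.5) dz, (j-0.5) dy, (k-0.5) dx)` micrometres.
* All lengths are micrometres; volumes are reported in mm³.
* Default voxel spacing is `(16, 4, 4)` µm: a ~16 µm translation step
  between planes, and a 10 mm field of view imaged on a 2,560-pixel
  detector in-plane.
* The equivalent diameter of a volume V is `d = (6V/π)^(1/3)`, the diameter
  of the sphere with the same volume.

## The morphometric quantities

**Volume.** `follicle_volume()` integrates the segmented whole-follicle
mask: voxel count × voxel volume. Every plane contributes, so irregularities
anywhere in the follicle are captured. On noiseless voxelized ellipsoids
spanning equivalent diameters 70 µm–2.5 mm the error is below 5% everywhere
and below 2% above 300 µm (it is pure surface discretization, so it shrinks
as the diameter grows).

**Equatorial plane.** 2D quantities are measured in the z-plane of maximal
cross-section area (`equatorial_plane()`, ties to the lowest index), which
avoids the off-equator underestimation that plagues physically sectioned
material.

**Asymmetry.** `equatorial_asymmetry()` fits the second-moment ellipse of
the equatorial cross-section in physical coordinates (so the 4 µm in-plane
vs 16 µm axial anisotropy cannot bias it) and returns the major/minor axis
ratio, ≥ 1. The raw second moments of pixel centres are augmented with the
square-pixel footprint term (`spacing²/12` per axis), which removes the
small-blob bias. Because "normalized ratio" admits two conventions, the
reciprocal (≤ 1) is also emitted (`asymmetry_minor_major`) so either can be
plotted. Collinear cross-sections are rejected as degenerate before the
footprint correction is applied.

**Wall thickness.** `theca_thickness_distribution()` takes, for each pixel
on the outer edge of the theca in the equatorial plane, the shortest
Euclidean distance to the inner edge in the same plane — the in-plane 2D
procedure, not a 3D surface distance, deliberately matching how such
measurements are read off individual image planes. Distances are computed
between pixel centres by a bucketed exact nearest-neighbour search (verified
bitwise against an all-pairs brute force in the tests). A boundary pixel's
centre sits on average half an in-plane pixel inside its surface, so one
in-plane pixel (half per edge) is added to the reported samples; with this
correction a digital concentric shell of true width 100 µm reads
100 ± 1 voxel with sub-voxel scatter. Sub-pixel edge interpolation is out
of scope; the tolerance budget is one in-plane voxel.

**Two-caliper estimate.** `orthogonal_diameter_estimate()` reproduces the
histology convention — longest chord through the cross-section centroid,
then a perpendicular chord through its midpoint, averaged. The chord search
uses boundary pixels within a 2° angular window, emulating a manual caliper
act rather than any published algorithm. The tests demonstrate that its
deviation from the volumetric equivalent diameter grows with asymmetry,
which is precisely the bias volumetric measurement avoids.

**COC sizing.** `coc_diameter()` selects the maximal-area (middle) plane of
the COC mask and reports the equivalent-circle diameter `2√(area/π)`.

**Staging.** `classify_stage()` uses equivalent-diameter thresholds:
primary < 100 µm ≤ antral ≤ 700 µm < Graafian. Both boundary values class
as antral (closed interval); the convention had to be fixed somewhere and is
documented here. Primordial candidates are only ever reported by the
egg-nest rule below, never by a diameter threshold alone.

## Segmentation

`segment_follicles()` runs: Gaussian denoising (default 5 µm sigma) →
global Otsu threshold of the bright shells (cleared-tissue and phantom
contrast are both near-bimodal; an absolute override exists) → 6-connected
morphological closing (1 voxel) → 3D filling of enclosed lumens →
26-connected component labelling → a distance-transform watershed split of
touching follicles → a minimum-size filter (default 40 µm equivalent
diameter). 26-connectivity for components with 6-connectivity (faces) for
boundary adjacency gives robust components and thin, consistent boundaries.

The watershed split only fires on components whose Euclidean distance
transform has at least two plateaus deeper than the merge tolerance
(default 60 µm); convex single follicles are skipped cheaply. Tie-breaks
between touching follicles follow the watershed of the 3D anisotropic
distance transform seeded at its maxima.

`extract_shell_masks()` decomposes each follicle: a per-follicle Otsu
threshold restricted to the outer rind (default 160 µm deep) compensates
brightness differences between follicles; the interior is whatever the
shell encloses (the segmentation halo ring is assigned to the exterior by
connectivity, not geometry); dark interior components that hug the shell
and stay thin are the delamination gap; the rest of the interior — granulosa
lining plus antrum — is the lumen. A shell that fails to enclose its
interior is reported as an error naming the follicle; a follicle whose
interior is under 5% of its volume is reported as solid (primary
morphology), which downstream code records as "no wall metrics" rather
than fabricating numbers.

`detect_cocs()` looks for bright, compact blobs in the lumen: a second Otsu
separates COC-bright voxels from the granulosa lining, a guard requires the
candidate class to sit well above the lining's own noise (mean + 5 sd —
otherwise the "second class" is just noise bisected), candidates must fall
in a 25–150 µm diameter band and be attached to the wall after a one-voxel
dilation. The largest attached blob is accepted; detached blobs are
reported only as candidates. On real tissue the COC and granulosa are the
same cell type and can be closer in intensity than the phantom paints them;
the brightness guard is then the first parameter to relax.

`discriminate_vessels()` separates blood vessels from follicles by
elongation: vessels extend through the stack while follicles appear and
disappear within a few planes. Components whose longest/second-longest
principal-axis ratio exceeds 4 are reclassified as vessels; single-voxel
components have an undefined ratio and stay follicles.

**Egg nests.** No diameter criterion separates primordial from primary
follicles in the literature values used here, so the package does not
invent one. Instead, small solid detections (40–100 µm, no resolvable wall)
that cluster — at least two similar neighbours within 300 µm — are flagged
`primordial` (counting only, no shell metrics). The clustering rule is this
package's own minimal operationalization of "egg nest" and is trivially
disabled.

## The phantom generator

`build_phantom()` renders a declarative scene (`phantom_spec()`) into a
16-bit stack plus a ground-truth manifest. Follicles are ovoids (rotated
ellipsoids) painted outer→inner: theca shell, delamination gap, granulosa
lining, antral lumen, optional COC sphere attached to the inner wall. Wall
thickness varies over the surface as a smooth degree-2 angular field with
amplitude `theca_thickness_modulation` (default 15% in the reference
scenes), so per-follicle thickness distributions are non-degenerate.
Vessels are capsules around polylines; egg nests are clusters of small
solid spheres. Structure overlap beyond a configurable tolerance (default
0 voxels) is an error — the measurement model assumes discrete follicles,
and zero tolerance keeps the ground truth unambiguous.

The imaging model applies, in order:

1. **Lateral blur**: isotropic Gaussian, 6 µm FWHM.
2. **Axial (light-sheet) blur**: per x-column Gaussian whose FWHM
   interpolates *linearly* from the waist thickness (default 11 µm; the
   16 µm calibration variant is a constructor argument) to 60 µm at 3 mm
   from the waist axis, clamped beyond. Only two calibration points exist,
   so a linear profile is used rather than forcing a Gaussian-beam
   hyperbola the data cannot distinguish. Kernels are edge-renormalized so
   constants stay constant; a kernel wider than the stack is an error.
3. **Noise**: detected electrons are Poisson with mean
   `level × photon_scale` (default 2000 e⁻ per unit level, giving an SNR of
   ~40 at the theca level), plus Gaussian read noise of 1.0 e⁻, referred
   back to the level scale — so a constant level L acquires variance
   `L/s + (σ_read/s)²`. The result is clipped at zero and quantized onto
   the 16-bit grid.

Intensities are abstract grayscale levels in [0, 1]
(theca 0.80 > granulosa 0.35 > background 0.08 > gap = lumen 0.02, COC
0.95): no radiometric calibration is attempted. The spec seed fully
determines the output — identical specs give bit-identical stacks and
manifests, which the determinism tests assert via file checksums.

The manifest records, per structure: analytic outer volume `(4/3)πabc`,
voxelized volume, the analytic major/minor ratio of the central z-plane
cross-section (via the Schur complement of the ellipsoid quadratic form),
the wall-thickness field sampled at 360 equatorial azimuths, COC diameter
and anchor, and the stage implied by the analytic equivalent diameter.

**What the phantom does not emulate** — and hence what passing tests do
not show about real tissue: refractive-index mismatch and depth-dependent
scattering, vignetting, multi-view fusion, clearing shrinkage beyond the
static delamination gap, intensity overlap between COC and granulosa,
atretic morphology, and stroma texture (the background is flat). Recovery
numbers on phantoms are an upper bound on real-data performance.

## Reference scenes and problem sizes

`cohort_phantom_spec()` is the standard validation scene: ten follicles
spanning equivalent diameters 74 µm–1.25 mm (two primary, five antral,
three Graafian), COCs of 50–110 µm on the six largest, in a
150 × 520 × 520 voxel volume (2.4 × 2.1 × 2.1 mm). Wall thickness follows
the physically realizable profile: thin in small early-antral follicles
(whose radius bounds the wall), peaking at ~120 µm in large antral
follicles, then falling to ~90 µm in the largest Graafian — so the inverse
thickness-vs-size relationship holds over the population on which wall
distributions are actually measurable (≥ 400 µm), which is also the
population such measurements are reported on. All diameters sit at
least 10% away from the 100/700 µm staging thresholds so staging accuracy
is well-defined under measurement noise. `demo_phantom_spec()` is a
smaller scene adding two vessels and a five-member egg nest. These sizes
were chosen so a full build–segment–measure–evaluate cycle runs in a few
minutes on a single core; the geometry spans the full size range the
measurement chain claims to handle.

`simulate_cohort_measurements()` is a separate *measurement-level*
simulator (no images): per-stage lognormal volumes whose medians and IQRs
follow the reported porcine per-stage statistics (primary 4.4×10⁻⁴,
antral 1.6×10⁻², Graafian 0.54 mm³), asymmetry and wall thickness with
inverse log-volume trends plus Gaussian noise, and oocyte diameters from a
saturating growth curve. It exercises the cohort statistics and regression
machinery at sample sizes (dozens per stage) that image rendering would
make needlessly expensive.

## Cohort statistics

`cohort_volume_summary()` reports n, mean, median and IQR of volume per
stage, formatted `mean [Q1–Q3]`; percentiles use linear interpolation
(R type 7), stated because IQRs at n ≈ 10 depend on the convention.

`fit_oocyte_growth()` fits oocyte diameter against follicle diameter.
The default family is the saturating hyperbola `o = a·d/(b+d)` — oocyte
growth plateaus in large follicles — with a log-linear alternative one flag
away. When a validation set is supplied (the literature-comparison design),
R² and adjusted R² are evaluated for the fitted curve *against the
validation points*; `adjusted R² = 1 − (1−R²)(n−1)/(n−p−1)` exactly.
Fitting uses Levenberg–Marquardt least squares; non-convergence is an
error, not a silent fallback.

`loglinear_regression()` is OLS of a response on log₁₀(volume), used for
the asymmetry-vs-size and thickness-vs-size analyses; both show negative
slopes on generated cohorts with the corresponding trends (the sign is
recovered in ≥95% of seeded runs at n = 20, which the acceptance tests
assert).

## Numerical choices and degenerate inputs

* Voxelization is centre-in-ellipsoid; no antialiasing. Volume error is
  therefore O(surface voxels) and strictly decreasing under grid
  refinement (asserted by a refinement test).
* Otsu thresholds are computed by EBImage on a 256-level histogram of the
  relevant voxel set (global, per-rind, or per-lumen).
* Empty stacks segment to zero labels (not an error); empty masks,
  non-positive volumes/diameters, unclosed shells, and missing spacing are
  errors that name the offending object.
* A stack with >20% of voxels at the intensity ceiling triggers a
  saturation warning.
* RNG: every stochastic step takes an explicit seed and restores the
  caller's RNG state; the phantom seed alone determines the stack.

## Known limitations

* Thickness is 2D-equatorial by design; a 3D surface-to-surface thickness
  map is out of scope.
* Atresia is not classified — no morphological criterion is available in
  the source measurements, and inventing one would be unfounded.
* The segmentation assumes bright-shell contrast; stains or modalities with
  inverted contrast need the absolute-threshold override.
* The two reported light-sheet waist calibrations (11 µm and 16 µm) are
  both exposed; the package defaults to 11 µm and takes no position on
  which is correct.
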