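---
title: "Markerless tumor tracking with orthogonal kV imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless tumor tracking with orthogonal kV imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotrack)
```

## The problem

Stereotactic radiotherapy of lung tumors must hit a target that moves with
every breath, typically 10-30 mm peak-to-peak and mostly along the
superior-inferior axis. Real-time tumor tracking (RTTT) systems localize the
tumor continuously during beam delivery; the established clinical solution
images 2-5 implanted gold fiducial markers with a pair of kV X-ray
tube/flat-panel chains and triangulates the marker centroids. Implantation
carries risk (pneumothorax, marker migration) and delays treatment, so a
*markerless* variant is attractive: predict the gross tumor volume (GTV)
contour directly on each projection image and triangulate the contour
centroids instead.

`orthotrack` implements that pipeline end to end, together with a synthetic
breathing-thorax phantom so that every stage can be exercised and scored
against exact ground truth without clinical data.

## Imaging geometry

The room frame has its origin at the isocenter with +x patient-left, +y
posterior-to-anterior, and +z inferior-to-superior. Each kV chain is modeled
by a point source on the axial ring at radius SID = 1000 mm, with a flat
panel 1836 mm (SDD) from the source. At tube angle 0 the source sits at
(0, -1000, 0) and the beam points along +y. The two chains of one gantry
pose sit at gantry angle +/-45 degrees, so their beam axes are exactly 90
degrees apart, the configuration that makes midpoint triangulation
well-conditioned.

The panel is a 1024 x 768 pixel grid. We fix the physical pixel pitch at
0.211 x 1836/1000 = 0.3874 mm so the pixel scale projected to the isocenter
plane is exactly 0.211 mm; the nominal 222 x 168 mm panel size quoted for
such systems is slightly inconsistent with 1024 x 0.211 = 216.1 mm at the
isocenter, and we treat the pixel scale and the array size as authoritative.

Training-set augmentation rotates the rigid source+panel assembly about the
isocenter by small angles: first a superior-inferior tilt about the panel's
horizontal axis, then an anterior-posterior tilt about the room z axis. The
composition order is a convention (the two tilts nearly commute at the
+/-3.5 degree amplitudes used); fixing SI-then-AP makes geometries
reproducible. Whether a clinical implementation would rotate only the source
or the whole chain is not observable from the DRR geometry at these
amplitudes; we rotate the assembly rigidly, which keeps the panel frame
orthonormal by construction.

## The breathing phantom

The phantom stacks, by voxel-center rasterization on a grid centered at the
isocenter: a body ellipsoid (default 0 HU), two lung ellipsoids (-750 HU), a
tumor ellipsoid, and optional marker spheres (3000 HU) rigidly co-moving
with the tumor. Defaults emulate the reported ten-patient cohort: a
spherical GTV of 7.42 cm^3 (semi-axis 12.1 mm; cohort median), tumor -176
HU (a mid-cohort mean GTV HU), a 22 mm 3D motion range dominated by SI
motion, 10 respiratory phases, 3 markers, and a 128 x 128 x 96 grid at 2 mm
isotropic spacing (the clinical slice thickness was 2-2.5 mm).
`table1_like_spec()` samples specs across the full reported ranges (GTV
volume 1.18-25.74 cm^3, motion 11-28 mm, mean HU -346 to -20, 2-5 markers).

Phase-binned 4DCT has no intrinsic waveform, so the phantom needs one to map
phase index to displacement. We use
$w(p) = \left[\tfrac{1}{2}(1 - \cos 2\pi p/N)\right]^k$ with $k = 2$: zero
at the end-exhale reference phase, unity at mid-cycle, with the
characteristic end-exhale dwell of free breathing. Hysteresis and
inter-phase deformation are deliberately absent; the tumor translates
rigidly. Consequences for interpretation: tests passing on the phantom
demonstrate the *geometric* correctness of rendering, labeling, matching and
triangulation, not robustness to deformation, 4DCT sorting artifacts,
scatter, or the DRR-vs-radiograph domain gap - the factors that dominate
clinical error budgets.

Rasterization uses the voxel-center-inside rule with no partial volume, so
masks and voxel counts are exactly reproducible; the price is a ~2%
fluctuation of the rasterized GTV volume around the analytic ellipsoid
volume as the tumor translates by sub-voxel amounts.

## DRR rendering

A projection pixel stores the radiological path $\int \mu\, dl$ along the
ray from the source through the pixel center. HU maps to attenuation by the
single-energy water-scaled line $\mu = \mu_w (1 + \mathrm{HU}/1000)$,
clamped at zero, with $\mu_w = 0.02$ mm$^{-1}$ (about 70 keV). The energy
model affects contrast only, never geometry, and no scatter, beam hardening
or detector physics are modeled.

The line integral is computed exactly for the piecewise-constant volume by
Siddon-style parametric traversal (incremental axis-crossing parameters,
half-open voxel intervals so plane crossings are unambiguous), implemented
in C++. The test suite checks it against an independent dense-sampling
(midpoint rule) oracle on random volumes and rays; the oracle step is
0.002 mm so the oracle's own quadrature noise stays an order of magnitude
below the 1e-3 comparison tolerance.

For display and template matching, the path image is mapped to 8 bits as
$\exp(-\mathrm{path})$ min-max rescaled per image. Rendering at
`downsample = d` traces one ray per $d \times d$ pixel block center,
giving an effective pitch of $d \cdot 0.3874$ mm. The package's own test
and acceptance runs use downsample 8 (128 x 96 pixels, 1.69 mm at the
isocenter) for full end-to-end runs and 16-64 for unit-level checks; full
1024 x 768 rendering is supported unchanged.

`gaussian_prefilter()` blurs a projection with an explicitly truncated
(4 sigma), normalized sampled Gaussian - the step used to match sharper
clinical projections to DRR resolution before prediction.

## Training-set factory

For one patient and one tube angle, every (phase, perturbation) pair yields
a sample: the original-volume DRR and the GTV-only DRR (all voxels outside
the GTV mask set to -1000 HU, so only the GTV attenuates) are rendered
under the identical perturbed geometry. The GTV mask on the projection is
the set of pixels with radiological path above 1e-6 - a threshold on path
rather than gray level, immune to display normalization. If the silhouette
fragments, the largest connected component is kept (single-GTV assumption);
an empty silhouette marks the sample invalid. The default grid of +/-3.5
degrees at 0.5-degree steps in both tilt directions gives 15 x 15 = 225
geometries, hence 2250 samples for a 10-phase 4DCT. Boundary polygons are
traced counterclockwise at pixel resolution; samples export to COCO-style
instance-segmentation JSON with one category.

## Contour prediction backends

The deployable contract is `fit_segmenter()` / `predict_contours()` /
`select_prediction()`. The reference backend is deterministic template
matching: each retained training sample contributes its mask-bounding-box
crop (dilated 2 px) as a template, and prediction maximizes zero-normalized
cross-correlation (ZNCC) over integer offsets in a search window around the
training location, translating the stored polygon and mask to the argmax.
Confidence is $(c + 1)/2$ for ZNCC $c$; predictions under the configurable
threshold (default 0.5) are dropped, and a frame with no surviving
prediction on either view contributes "no prediction" to the
prediction-rate denominator. A learned instance-segmentation model (the
approach used clinically) slots behind the same contract; it is not
required by any test, because trained weights are not reproducible at desk
scale while the surrounding pipeline is.

A note on the confidence scale: the maximum of ZNCC over a search window on
pure noise is almost surely positive, so the default 0.5 threshold (ZNCC 0)
does not reject noise-only images; rejection thresholds should be
calibrated against a null distribution, as the test suite demonstrates
(noise maxima stay well below the self-match confidence of 1.0).

## 3D positioning

Both the markerless method and the simulated marker-based reference use the
same primitive: given one ray per view (source through the contour centroid,
or through the mean of the marker detections), the 3D position is the
midpoint of the shortest segment between the two rays, obtained in closed
form from the 2 x 2 normal equations. Near-parallel rays (cross-product
norm below 1e-9) are rejected. The silhouette centroid of a projected body
is not exactly the projection of its 3D centroid for asymmetric shapes;
this bias is inherent to the method and vanishes for the phantom's
ellipsoids.

Two error bounds organize the tests: noiseless sub-pixel centroids of a
point target reproduce the 3D point to < 1e-6 mm (the rays intersect by
construction), and whole-pixel quantization of the detections bounds the 3D
error by $\sqrt{2}$ x (isocenter pixel scale), about 0.30 mm at the
clinical geometry. The marker-based reference adds the stored reference
offset (marker center-of-mass to GTV at the reference phase) after
triangulation; marker "detection" in simulation is forward projection with
optional pixel quantization and jitter - image-processing blob detection is
out of scope.

## Evaluation statistics

A tracking run's report follows the clinical accounting: of all stored
orthogonal frame pairs, some have a marker-based position, some a
markerless position (both views predicted), and the intersection with valid
ground truth forms the compared set on which 3D deviations (Euclidean, at
common timestamps) are summarized. Quartiles use linear interpolation
between order statistics (type 7); the cumulative curve uses the <=
convention with 3 mm and 5 mm always reported. Pearson correlations relate
per-patient median deviation and prediction rate to GTV volume and motion
range, and per-fraction summaries to fraction index, optionally recomputed
with one patient excluded to probe outlier leverage.

The package ships the published summary tables of the ten-patient cohort as
plain-text inputs (`cohort_summary()`); `cohort_correlations()` reproduces
the published correlation coefficients from them to within the precision
the printed tables support (the deviation-vs-volume coefficient is the one
quantity that evidently requires unrounded per-patient values).

## Numerical and design choices

* Degrees in all interfaces, radians internally; angles normalized to
  [0, 360).
* Voxels are axis-aligned boxes; world coordinates are
  origin + index * spacing with 0-based indices.
* Ties and degeneracies: half-open traversal intervals in the ray tracer;
  stable (first-wins) tie-break among equal-confidence predictions;
  rejection with typed conditions for empty silhouettes and parallel rays.
* The end-to-end driver fans one global seed out to per-stage streams by
  stable hashing of stage names, so runs are byte-identical given
  (config, seed).
* Problem sizes in the shipped tests and acceptance script: 8 mm / 32^3
  phantoms for counting checks, 4 mm / 64^3 for tracking unit tests, and
  the default 2 mm / 128x128x96 phantom with downsample-8 rendering and a
  +/-1 degree training grid for the end-to-end run - sizes chosen so a
  complete run is a desk-scale computation while every stage runs at full
  fidelity of logic.

## Known limitations

* The phantom has no deformation, hysteresis, rib/diaphragm anatomy,
  scatter or imaging noise; clinical deviation magnitudes are not
  reproduced, only the geometric pipeline is validated.
* The template backend assumes the treatment-time appearance matches the
  DRRs up to translation; it is a reference implementation of the contract,
  not a clinical-grade predictor.
* DICOM support is a deliberately minimal explicit-VR little-endian subset
  (CT image series and RT structure sets); it round-trips its own output
  and is cross-checked against an independent reader, but it is not a
  general DICOM implementation.
* No latency modeling or future-position prediction: timestamps are carried
  through, not extrapolated.
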