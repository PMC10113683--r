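# orthotrack

Markerless real-time tumor tracking (RTTT) for lung radiotherapy with an
orthogonal kV imaging system, as a reusable, testable R pipeline.

Clinical RTTT systems localize a breathing lung tumor by imaging 2-5
implanted gold markers with two kV X-ray tube / flat-panel chains mounted at
gantry angle ±45° (beam axes 90° apart, SID 1000 mm, SDD 1836 mm, 1024×768
panel, 0.211 mm/pixel at the isocenter) and triangulating the marker
centroids. The markerless alternative implemented here predicts the gross
tumor volume (GTV) contour directly on each projection image and
triangulates the contour centroids instead:

1. **Training-set factory** — from a 10-phase 4DCT (DICOM CT series +
   RT-STRUCT, or the package's synthetic breathing phantom), render paired
   original and *GTV-only* digitally reconstructed radiographs (DRRs) by
   Siddon ray tracing under a grid of small beam-angle perturbations
   (±3.5° at 0.5° steps in the superior-inferior and anterior-posterior
   directions: 15 × 15 = 225 geometries, so 10 phases give **2250 labeled
   samples per tube angle**); the GTV mask is extracted from the GTV-only
   DRR and overlaid on the original DRR as an instance label.
2. **Per-patient, per-tube-angle contour predictor** — a pluggable
   `fit/predict` contract with a deterministic template-matching (ZNCC)
   reference backend; a learned instance-segmentation backend fits behind
   the same contract.
3. **Stereo positioning** — the 3D position is the midpoint of the shortest
   segment between the two source-to-centroid rays,
   $\min_{t,s}\,\lVert (o_a + t d_a) - (o_b + s d_b)\rVert$, solved in
   closed form; the marker-based clinical reference (marker-centroid
   triangulation plus the reference-phase marker-to-GTV offset) is
   simulated alongside as ground-truth machinery.
4. **Evaluation statistics** — 3D deviation distributions (median, IQR,
   cumulative percentage curve), prediction/detection rates with the
   clinical frame accounting, and Pearson correlations of per-patient /
   per-fraction summaries against cohort covariates.

A synthetic 10-phase breathing-thorax phantom (body + lungs + tumor
ellipsoids + markers, cos²-waveform motion, analytic ground-truth track)
emulates the reported ten-patient cohort (GTV 1.18-25.74 cm³, motion
11-28 mm, mean GTV HU -346 to -20) so every stage is testable without
clinical data.

## Worked example

```r
library(orthotrack)

cfg <- run_config(
  phantom    = phantom_spec(grid_shape = c(64, 64, 48), spacing_mm = c(4, 4, 4)),
  grid       = make_grid(1, 1),     # ±1° training perturbations
  downsample = 16,                  # render 64×48 px projections
  n_frames   = 20, seed = 42)
run <- run_end_to_end(cfg)
print(run$report)
#> evaluation_report: 20 frame pairs, 20 marker-detected (100.0%), 20 predicted (100.0%), 20 compared
#>   3D deviation: median 0.86 (IQR 0.54-1.24) mm
#>   <= 1 mm: 70.0%
#>   <= 2 mm: 100.0%
#>   <= 3 mm: 100.0%
#>   <= 5 mm: 100.0%
```

Every one of the 20 simulated orthogonal frame pairs produced a contour on
both views (prediction rate 100%), and the triangulated markerless track
deviates from the phantom's analytic tumor trajectory by a median of
0.86 mm — well below the 3.4 mm isocenter pixel scale of the deliberately
coarse 16× downsampled rendering, i.e. the pipeline recovers the breathing
motion to sub-pixel accuracy. `run$track_markerless`, `run$track_marker`
and `run$track_truth` hold the timestamped (x, y, z) tracks in mm.

The individual stages are exported too: `generate_phantom()`,
`read_ct_series()` / `extract_gtv_mask()` / `gtv_only_volume()`,
`render_drr()`, `build_training_set()` / `export_annotations()`,
`fit_segmenter()` / `predict_contours()`, `triangulate_midpoint()` /
`marker_ground_truth()`, and `build_report()`. A thin command-line wrapper
lives at `inst/cli/orthotrack.R` (`run-all`, `phantom`, `evaluate`).

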