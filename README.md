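# standmetrics

Seedling stand reconstruction and sowing-quality evaluation from top-view
depth imagery.

## What problem this solves

Precision planters are judged by how evenly they place seeds along the
row. After emergence, the quantity that matters agronomically is the
spacing between *seedlings* — which differs from seed drop spacing because
of emergence failures and double drops. `standmetrics` measures within-row
plant spacing from the output of a camera rig driven over the crop: a
nadir (straight-down) stereo camera on a moving platform produces, per
frame, plant keypoint detections (bounding box + one reference keypoint +
confidence) and a depth map. The package turns those into a metric 3D
reconstruction of the stand and scores it with the ISO 7256/1-1984
seeding-quality indices.

The intended users are agricultural engineers and phenotyping researchers
evaluating planter performance or building field measurement rigs.

## The measurement chain

1. **Frame alignment.** RGB frame `t` is paired with depth frame
   `floor(t · f_depth / f_rgb)`.
2. **Robust depth.** The depth at a detection is the median of the valid
   pixels in a small window (default 3×3) around the keypoint; pixels
   where stereo matching failed (value 0 / NaN) are excluded, and a fully
   invalid window yields a missing reading that later frames compensate.
3. **Back-projection.** With intrinsics `(f_x, f_y, c_x, c_y)`, a keypoint
   pixel `(x, y)` at depth `z` becomes
   `X = (x − c_x) z / f_x`, `Y = (y − c_y) z / f_y`, `Z = z`.
4. **Tracking.** Detections are associated across frames by a motion-gated
   greedy nearest-neighbour tracker: after adding the platform
   displacement to the along-track coordinate, a static plant is
   stationary in world coordinates, so each detection joins the nearest
   live track within a gate (default half the target spacing). Each
   plant's position is the coordinate-wise median of its observations.
5. **Rows and spacings.** Plants are clustered into rows by cross-track
   gaps, ordered along-track, and the spacing `d_i` is the 3D Euclidean
   distance between consecutive keypoints.
6. **Quality indices.** With normalized ratios `S_i = d_i / d_ref` binned
   into `[0, 0.5]`, `(0.5, 1.5]`, `(1.5, 2.5]`, `(2.5, 3.5]`, `(3.5, ∞)`
   (counts n′1…n′5), the seeding counts are

   ```
   n2 = n′1                       (multiples)
   n0 = n′3 + 2 n′4 + 3 n′5       (misses)
   N′ = n′2 + 2 n′3 + 3 n′4 + 4 n′5
   n1 = Σ n′i − 2 n2              (normal seedings)
   QFI = 100 n1/N′   MUL = 100 n2/N′   MI = 100 n0/N′
   ```

   and the qualified-spacing dispersion is `CV = 100 σ` with `σ` the
   population SD of the ratios in `(0.5, 1.5]`. QFI + MUL + MI = 100 by
   construction.

A synthetic field simulator (`simulate_stand()`, `render_observations()`)
generates planted rows with miss/multiple events, spacing jitter,
detection noise, depth noise and dropout, together with exact ground
truth, so the whole chain is testable without field data.

## Worked example

```r
library(standmetrics)

run_dir <- file.path(tempdir(), "demo")
simulate_run(stand_config(target_spacing = 0.20, n_positions = 101,
                          p_miss = 0.1, p_multiple = 0.05, seed = 42),
             acquisition_config(seed = 43),
             dir = run_dir)

m <- run_pipeline(run_dir, pipeline_config(target_spacing = 0.20),
                  verbose = FALSE)
print(m)
```

```
stand_measurement: 91 plants, 1 row(s), 90 spacing intervals
Sowing quality (ISO 7256/1-1984 indices)
  spacings: 90, target: 0.2 m
  QFI 88.00%  MUL 1.00%  MI 11.00%
  S_bar 1.0111  sigma 0.0839  CV 8.39%
  intervals N' = 100 (n1 88, n2 1, n0 11)
```

Reading: of the 100 effective seeding intervals, 88% were normally
spaced, 1% were double placements (interval ≤ half the target) and 11%
were misses (each gap of ≈ k+1 targets counts k misses). The qualified
intervals scatter around the target with a coefficient of variation of
8.4%. For this simulated stand the ground-truth report
(`truth.json` in `run_dir`) gives the same three indices, so the
measurement chain recovered the stand exactly.

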