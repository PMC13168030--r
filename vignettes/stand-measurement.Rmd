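---
title: "Measuring plant spacing and sowing quality from top-view depth imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring plant spacing and sowing quality from top-view depth imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standmetrics)
```

## The measurement model

A nadir stereo camera rides a platform moving at constant speed along a
planted row, emitting an RGB stream (from which a detector produces per
plant a bounding box, one reference keypoint and a confidence) and a
depth stream in millimeters with dropouts where stereo matching failed.
`standmetrics` reconstructs each plant's metric 3D position and evaluates
the stand against the planter's target spacing.

The chain is deliberately simple and fully deterministic:

* **Temporal alignment** pairs RGB frame $t$ with depth frame
  $\lfloor t \cdot f_{depth}/f_{rgb} \rfloor$. Both rates are config
  values: acquisition rigs of this kind run anywhere between 15 and
  30 fps, and the two streams need not match.
* **Depth extraction** takes the median of the valid pixels in a square
  window (default $3\times3$ px) centred, by default, on the keypoint
  pixel. The window is clipped at image borders rather than padded —
  padding would fabricate depth. A window with no valid pixel yields a
  missing reading.
* **Back-projection** applies the ideal pinhole inverse
  $X = (x-c_x)z/f_x$, $Y = (y-c_y)z/f_y$, $Z = z$. Lens distortion is
  not modelled.
* **Tracking** maintains one identity per plant across the tens of
  frames in which it is visible. After ego-motion compensation (adding
  the platform displacement to the along-track coordinate) a static
  plant is a fixed world point, so association is greedy
  nearest-neighbour matching against each live track's running
  coordinate-wise median, gated at a configurable radius. Ties break by
  ascending distance, then track id, then detection order, making runs
  bit-reproducible.
* **Row assignment** clusters world positions by cross-track gaps. The
  per-image "horizontal strip" view of row separation is the projection
  of this world-frame partition; clustering in world coordinates makes
  it independent of where each frame happened to be taken.
* **Spacing** is the 3D Euclidean distance between consecutive keypoints
  within a row. Because it is a 3D distance it includes the height
  difference between neighbouring plants; with realistic height
  variation (SD ≈ 2 cm) this inflates spacings by only a few millimeters
  but it is visible in high-precision scenarios.

### Why sample depth at the keypoint?

The 3D point being reconstructed is the keypoint, so depth is sampled
there by default: sampling at the bounding-box centre and back-projecting
the keypoint would mix two viewing rays and introduce parallax error.
Rigs that prefer the box centre (e.g. because the keypoint sits on thin
plant matter with unreliable stereo) can set
`depth_anchor = "bbox_center"`.

## The quality indices

Measured spacings $d_i$ are normalized by the target $d_{ref}$,
$S_i = d_i/d_{ref}$, and classified into five intervals: $[0, 0.5]$
(double placements), $(0.5, 1.5]$ (qualified), and $(1.5, 2.5]$,
$(2.5, 3.5]$, $(3.5, \infty)$, where an interval of length $\approx k+1$
targets hides $k$ misses. With counts $n'_1 \dots n'_5$:

$$n_2 = n'_1, \quad n_0 = n'_3 + 2n'_4 + 3n'_5, \quad
  N' = n'_2 + 2n'_3 + 3n'_4 + 4n'_5, \quad n_1 = \textstyle\sum_i n'_i - 2n_2$$

$$\mathrm{QFI} = 100\,n_1/N', \quad \mathrm{MUL} = 100\,n_2/N', \quad
  \mathrm{MI} = 100\,n_0/N'.$$

The identity $n_1 + n_2 + n_0 = N'$ holds for every input, so the three
indices always sum to 100%. The definition of $n_2$ as the count of
short intervals is the only assignment under which that identity holds,
and it matches ISO 7256 semantics: a double placement splits one seeding
interval into two short ones, consuming one extra interval.

Dispersion is reported on the qualified ratios only:
$\bar S$ = mean, $\sigma$ = *population* standard deviation about
$\bar S$, $\mathrm{CV} = 100\sigma$. Two auditing switches exist:
`sigma_formula = "as_printed"` computes the raw second moment
$\sqrt{\sum S_i^2/n'_2}$ instead (not a dispersion measure — for ratios
near 1 it sits near 1, i.e. CV near 100%, which is why it is not the
default), and `cv_normalize_by_mean = TRUE` reports the classical
$100\sigma/\bar S$; since $\bar S \approx 1$ by construction the
difference is second order.

### Numerical choices

* Ratios are quantized at $10^{-6}$ before binning and statistics. The
  quantum is three orders of magnitude below the measurement precision
  (millimeters over decimeters), so no information is lost, and it makes
  the whole quality report exactly invariant to the unit in which
  spacings and target are expressed — raw IEEE division is not.
* Interval boundaries belong to the lower bin ($S = 0.5$ is a double,
  $S = 1.5$ qualified), so boundary ratios classify deterministically.
* $n_1 < 0$ (possible when short intervals dominate) is reported as-is
  with `valid = FALSE` and a warning rather than clamped — clamping
  would hide a pathological stand.
* Degenerate inputs error explicitly: an empty spacing series, and
  $N' = 0$ (every spacing in the multiples bin).
* Text outputs serialize with 9 significant digits; rounding to the
  2-decimal presentation happens only in `print()`/`report`.

## The synthetic field simulator

No public dataset exists for this acquisition geometry, so the package
ships a generative stand/camera simulator used by all end-to-end tests.

`stand_config()` describes the planter outcome: nominal drop points at
the target spacing; each empty with probability `p_miss` (lengthening
the neighbouring gap, exactly the event MI weights); otherwise one plant
with Gaussian along-track placement jitter, plus with probability
`p_multiple` a second plant at a small Gaussian offset (the short-gap
event MUL counts). `acquisition_config()` describes the rig: intrinsics,
mount height, speed, stream rates, keypoint pixel jitter, Gaussian depth
noise, per-pixel depth dropout, and detector confidence range.

Defaults mirror a field rig of the kind the package targets: camera
1.15 m above ground, 2 km/h (0.556 m/s), 30 fps on both streams, target
spacing 0.20 m, placement jitter 1 cm, `p_miss` 0.1, `p_multiple` 0.05
with 3 cm double-drop offsets, plant keypoint height 0.30 ± 0.02 m,
depth noise 12 mm (≈1% of range, the accuracy class of consumer stereo
heads at this distance) and 2% depth dropout. The default sensor is a
desk-scale 160×120, $f = 150$ px camera whose footprint at 1.15 m
matches a much larger real sensor; resolution is a config value, and the
small default keeps simulated depth streams light (a 100-plant pass is
~1100 frames). The rendered plant is a compact square of canopy depth
around the keypoint (radius 3 cm — the visually stable whorl core, not
the full leaf span), and a detection is emitted only when the whole box
is inside the frame, as partial detections at frame edges are unreliable
in practice.

Two independent RNG streams (stand vs rendering) are sub-seeded
separately, so changing acquisition noise never changes the simulated
stand. Ground truth (`truth.json`) stores plant positions, true
spacings, and the oracle quality report computed from the true spacings
with the same evaluator — labelled synthetic throughout.

**What the simulator does not emulate:** photorealistic appearance, leaf
morphology and overlap, real occlusion (only detection-box suppression
of very close doubles), correlated depth artifacts, platform pitch/roll,
and GNSS drift. Passing end-to-end tests therefore demonstrate that the
geometry, tracking and index chain is correct under the stated noise
model — not that a particular detector or stereo head meets a given
field accuracy.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `conf_min` | 0.5 | – | detection confidence gate |
| `iou_max` | 0.5 | – | NMS overlap threshold |
| `window` | 3 | px | depth median window side |
| `depth_anchor` | keypoint | – | where depth is sampled |
| `gate` | target/2 | m | tracker matching radius |
| `max_age` | 5 | frames | track survival without a match |
| `row_gap` | 0.3 | m | cross-track gap separating rows |
| `aggregate` | median | – | per-track position statistic |

The gate default of half the target spacing is the largest radius that
cannot confuse two correctly spaced neighbours; the median aggregate is
robust to occasional identity switches. Confidence and NMS defaults are
conventional detector settings, not calibrated values.

## Design decisions that were genuinely open

* **Tracker.** Appearance-based re-identification (as in
  DeepSORT-style trackers) needs a trained embedding; the package
  implements a motion-only stand-in that preserves the contract the
  pipeline needs — one identity per plant, resistance to short dropouts
  — and is exact under ego-motion compensation. It is a behavioural, not
  algorithmic, equivalent of appearance-augmented tracking.
* **World fusion.** How per-frame camera positions fuse into one
  along-row coordinate system is not dictated by the acquisition
  geometry alone; the package uses the platform displacement model
  (constant speed or an explicit per-frame table) as the world
  transform, and the coordinate-wise median as the fusion statistic.
* **Per-row vs pooled evaluation.** Both are reported
  (`reports_per_row` and the pooled `report`); pooling weights every
  interval equally, per-row reporting exposes row-to-row variation.
* **Frame rate.** Rigs of this class are operated anywhere from 15 to
  30 fps; the rate is a config value with a 30 fps default.

## Problem sizes

The shipped tests run the full chain at stand sizes of 10–100 plants
(plus one 500-position stochastic stand) with the default desk-scale
sensor; at those sizes a complete simulate-and-measure cycle takes
seconds. The same code paths scale linearly in frames and detections for
field-scale runs.

## Known limitations

* The pinhole model ignores lens distortion; rigs with wide-angle optics
  should undistort upstream.
* Row clustering assumes rows are parallel to the travel direction;
  strongly curved rows would need a curvilinear row model.
* The tracker's greedy one-to-one matching can momentarily swap
  identities of plants closer than the gate; the median aggregate
  bounds the damage but extremely dense doubles (< 2 cm) may merge
  under detection NMS.
* MI/MUL are interval statistics: they cannot distinguish a true miss
  from a germination failure, nor a double drop from two seeds of
  adjacent intervals drifting together.
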