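---
title: "Methods: behavioral phenotyping from pose-estimation trajectories"
author: "skeletrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral phenotyping from pose-estimation trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skeletrack)
```

## Overview

Markerless pose estimators such as DeepLabCut turn behavioral videos into
per-frame tables of keypoint coordinates with a tracker confidence
("likelihood") per sample. `skeletrack` implements everything downstream of
that table for the three classic rodent assays — open field test (OFT),
elevated plus maze (EPM) and forced swim test (FST):

1. **Cleaning** — likelihood gating and gap interpolation.
2. **Arena reconstruction** — the arena is rebuilt *in silico* from tracked
   landmark points, and the pixel scale is calibrated against the measured
   physical arena size.
3. **Kinematics** — speed, acceleration, distance, zone occupancy,
   occupancy maps, head angle.
4. **Rule-based ethological detectors** — floating (FST) and head dips
   (EPM), plus the generic bout-segmentation rules shared by all behaviors.
5. **Supervised classification** — a position- and orientation-invariant
   22-dimensional skeletal representation feeds a small fully connected
   network that classifies supported and unsupported rears frame by frame,
   evaluated by leave-one-video-out cross-validation.
6. **A synthetic-session generator** that emulates a 13-keypoint mouse with
   scripted ground-truth behavior bouts, so the entire pipeline is testable
   without any video data.

Coordinates are image coordinates throughout: origin top-left, y grows
downward. The one place this matters — the sign of angles — is handled
internally so reported signs are anatomical (positive = toward the
animal's left).

## Cleaning

Tracker output contains confident samples and occasional failures
(occlusions, reflections). Samples with likelihood below a cutoff
(default **0.95**, the conventional DeepLabCut gate) are discarded and
re-estimated by **linear interpolation** between the nearest valid
neighbors, per keypoint and axis; leading and trailing invalid runs hold
the nearest valid value. Linear interpolation is the simplest method
consistent with the short, scattered gaps typical of good tracking; no
smoothing is applied to valid samples, so the cleaned track is the raw
track wherever the tracker was confident. The operation is idempotent, and
the fraction of imputed frames is attached as a diagnostic — long
interpolated stretches are straight lines, not behavior, so a
`max_gap_frames` warning threshold is available (default unlimited, with
the diagnostic left to the analyst).

## Arena reconstruction and calibration

Arena landmarks are physically static, so each landmark's position is the
per-axis **median** over all confidently tracked frames — immune to
occasional glitches. The pixel scale follows from comparing the area of
the reconstructed arena polygon (px²) with the measured physical area
(cm²): `px_per_cm = sqrt(area_px / area_cm)`. Because the arena is
re-detected per video, the calibration survives camera or arena shifts
between sessions.

Zones are derived from the arena polygon:

* **Proportional zones** use polygon scaling: shrinking the polygon about
  its area centroid by `sqrt(f)` encloses exactly the fraction `f` of the
  original area. The OFT center is the 50% scaling of a 45 × 45 cm arena:
  1012.5 cm².
* **Distance-based zones** use a true inward edge offset, not area
  scaling, because a reach criterion is a distance: the supported-rear
  wall band is the ring within 12.5 cm of the walls (for the 45 cm arena
  the interior remainder is a 20 × 20 cm square). The offset is exact for
  convex polygons, which covers all shipped templates.
* The **EPM** template takes 12 landmarks (two end corners per arm, four
  centre-square corners) and builds five zones: two open arms, two closed
  arms (65.5 × 5.5 cm each) and the 5.5 × 5.5 cm centre. Arm quadrilaterals
  join each pair of end corners with the two nearest centre corners, which
  makes the construction invariant to camera rotation. On a shared arm/centre
  edge, the arm wins (zone priority order in `assign_zone()`).
* The **FST** beaker outline is a least-squares circle fit (Kåsa method)
  to three or more rim landmarks, represented as a 64-gon.

Point-in-zone tests use the even-odd rule with boundaries counting as
inside; ring-shaped zones (wall band, periphery) are an outer polygon
minus holes, with hole boundaries belonging to the ring.

## Kinematics

Speed at frame *f* is the Euclidean step from the previous frame times the
frame rate; acceleration is the first difference of speed times the frame
rate (the first two frames are zero by convention, before two speed
samples exist); distance is the running sum of steps. All are computed per
keypoint; session summaries use a configurable reference point
(`body_centre` by default). The head angle is the signed angle between the
body axis (tail base → neck) and head axis (neck → nose), positive toward
the animal's left, range (−180°, 180°]; frames with a degenerate axis are
missing.

## Bout segmentation

All behaviors share one event model: per-frame flags are segmented into
bouts by first **merging** true-runs separated by gaps of at most
`merge_gap_ms` (a recurrence that quickly follows a bout counts as part of
it) and then **discarding** merged runs shorter than `min_duration_ms`.
Both default to **150 ms**, the convention used for rear scoring in
beam-grid systems. Merging before filtering prevents one real bout,
fragmented by a flicker, from being discarded piecewise. The
implementation is property-tested against a brute-force scan-and-merge
reference on thousands of random sequences at 25 and 30 fps.

## Floating detector

Floating (immobility in the FST) is detected from the dynamics of the
**body-outline polygon area** — the shoelace area of the polygon through
nose, ears, flanks, hips and tail base. While the mouse paddles, limb and
trunk motion churn this area; when it floats, the outline freezes.

The statistic is the per-frame **absolute rate of change of the area**,
relative to the session-median area (units: fraction of median area per
second). Two numerical choices matter, and both exist because a raw
single-frame increment is a poor boundary discriminator:

* The per-frame rate is the **RMS of `rate_window_frames = 4` consecutive
  increments** (a 5-frame centered window). A single area increment can be
  near zero mid-swim whenever the outline happens to pass through an
  extremum — its distribution is dense at zero for the mobile class too —
  whereas the pooled RMS almost never is. Pooling turns the two classes
  into well-separated scale distributions.
* The rate series is then smoothed with a **centered running median**
  (`smoothing_window_frames = 25`, about 1 s at 25 fps), a robust local
  dispersion estimate that single-frame artifacts (interpolation kinks,
  bout transitions) cannot drag across the threshold. Because a step
  change in mobility flips the window's majority right at the boundary,
  the wide window does not delay detected bout edges.

Frames whose smoothed rate falls below `rate_threshold` are flagged and
segmented as above. The threshold default (**2.0** median-area fractions
per second) was calibrated once on the synthetic generator under its
default noise conditions — floating frames sit at the tracker-noise floor
(well below 1), paddling drives the statistic severalfold above the
threshold — and is configurable per experiment; on real videos it should
be checked against a few manually scored sessions.

## Head-dip detector

A head dip is flagged when the **nose is off the maze surface** (outside
every EPM zone) **while the head centre is on an open arm**. The open-arm
gate excludes nose excursions along closed-arm walls and at the centre.
Flags pass through the same 150 ms / 150 ms segmentation.

## Skeletal representation (22 features)

The classifier does not see coordinates; it sees a per-frame vector that
is invariant to where the animal is and which way it faces — 11 segment
lengths (head, trunk and tail segments, ear/flank/hip widths, nose–tail
and neck–tail spans), 6 signed joint angles (head deflection, body bend,
tail bend, ear-axis, hip-axis and head-axis orientation relative to the
body axis), 3 polygon areas (head, trunk, whole body) and 2 shape ratios
(width/length elongation, head/trunk length). Under reflection, lengths,
areas and ratios are unchanged and signed angles negate — a property the
test suite checks exactly. Degenerate frames (coincident points) yield
zeros by convention. The list is fixed and versioned
(`skeleton_feature_names()`); any change bumps the schema version stored
in trained bundles.

For immobility-type behaviors a second representation is available: the
13 per-keypoint acceleration magnitudes, which capture motion energy
where the pose itself is uninformative.

## Classifier and evaluation

Behaviors are recognized from **short sequences**, not single frames: each
sample concatenates the features of a centered window (default 15 frames,
~0.6 s at 25 fps; edges replicate the terminal frame) and takes the center
frame's label. The network is a fully connected **256 → 128 → labels**
architecture with ReLU units, trained with Adam on cross-entropy weighted
by inverse class frequency (the background class dominates any honest
frame labeling). Inputs are standardized with training-fold statistics
only, which travel with the model bundle. Training is deterministic given
the seed. Hyperparameter defaults (30 epochs, batch 128, learning rate
1e-3) are deliberately plain; the architecture, not the schedule, is the
designed object.

Evaluation is **leave-one-video-out**: for k videos, train on k−1,
evaluate frame-to-frame accuracy on the held-out video, and compare
per-behavior event counts (obtained from predicted labels via the standard
segmentation) against the held-out annotation. Agreement across raters or
systems is summarized with the Pearson correlation of per-video scores and
the coefficient of variation (sd/mean × 100).

## The synthetic generator

`simulate_session()` emits a DLC-format table plus ground-truth
annotations for a scripted scenario. A rigid 13-point template
(~11 cm nose-to-tail-base, ~2.8 cm wide) follows a bounded AR(1) random
walk (mean speed ≈ 7–10 cm/s, giving ~40–60 m per 10-min OFT session)
with smoothed heading; landmarks are emitted as constant points plus
noise; every coordinate gets Gaussian tracker jitter (default 0.5 px) and
a `dropout_rate` fraction of samples (default 2%) get likelihood 0.1 and a
large uniform coordinate jump, so interpolation is genuinely exercised.
Scripted bouts deform the template deterministically:

* **supported rear** — the animal pauses within the wall band and its
  body axis compresses to 65% (top-view foreshortening with forepaws on
  the wall);
* **unsupported rear** — pause in the interior, axis compresses to 45%
  with the nose tucked over the body centre (a full upright rear
  foreshortens more);
* **floating** — the swim-stroke modulation stops and the pose freezes;
* **head dip** — the nose displaces 1.5 cm beyond the open-arm side edge
  while the head centre stays on the arm.

Swimming is modeled as a 2.5 Hz stroke modulating the outline by ±15%,
plus an AR(1) broadband component and independent per-frame limb jitter of
0.8 cm (~20 cm/s instantaneous limb speed — vigorous paddling). The
broadband terms are essential realism: a pure sinusoid has a derivative
that lingers at zero every half-period, which no real swim does.

The generator is seeded and is the only randomness source; identical
scenarios are bit-identical. What it does **not** emulate: biomechanics
(deformations are parametric ramps, not physics), thigmotaxis (the walk
has no wall preference, so zone occupancies carry no biological meaning),
grooming or other unscripted behaviors, multi-animal scenes, and video
itself. Tests passing on synthetic sessions therefore demonstrate that the
pipeline recovers known ground truth under realistic tracking noise — not
that the default thresholds are optimal for any particular real dataset.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen to
exercise every code path in minutes on one CPU: 60–120 s sessions at
25 fps, six 60 s videos for the leave-one-video-out experiment (~9,000
evaluated frames per run), 1,000-case invariance and polygon-scaling
sweeps, and a 10,000-sequence segmentation oracle comparison. Full-length
(10 min) sessions run through the identical code path via
`make_fixture_suite()`.

## Known limitations

* The wall-band offset assumes a convex arena polygon.
* The floating threshold, like any immobility cutoff, is a per-setup
  calibration; the default is anchored to the generator's noise model.
* The EPM centre construction and the concrete 22-feature list are
  documented conventions of this package; other reasonable choices exist,
  which is why both are versioned and configurable.
* Supported/unsupported rear separation is learned from the invariant
  skeleton alone. For datasets where the postural difference is weaker
  than the spatial one, predicted rears can be cross-checked against
  wall-band occupancy (`assign_zone()` with the `wall_band` zone), which
  is the criterion beam-grid systems use.
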