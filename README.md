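# skeletrack

Behavioral phenotyping from markerless pose-estimation trajectories.

Pose estimators such as DeepLabCut reduce a rodent behavior video to a
table of per-frame keypoint coordinates with tracker confidences. Turning
that table into the numbers a behavioral neuroscientist reports — distance
traveled, time in the anxiogenic center of an open field, open-arm time
and head dips on an elevated plus maze, floating time in a forced swim
test, supported and unsupported rears — takes a post-analysis pipeline:
confidence gating and interpolation, in-silico arena reconstruction and
pixel-to-cm calibration, zone geometry, kinematics, bout segmentation,
rule-based detectors, and supervised behavior classifiers. `skeletrack`
implements that pipeline for R.

Who it is for: labs that track mice (13-point skeleton: nose, head
centre, ears, neck, body centre, flanks, hips, tail base/centre/tip) in
the open field test (OFT), elevated plus maze (EPM) or forced swim test
(FST), and want commercial-system-grade tracking measures plus
human-grade ethological scoring from their own annotations.

## The methods in brief

* **Cleaning**: keypoint samples with tracker likelihood `< 0.95` are
  removed and re-estimated by linear interpolation in time (nearest-value
  hold at the edges).
* **Arena in silico**: static landmark points are reduced to per-axis
  medians; the pixel scale is `sqrt(area_px / area_cm)` from the measured
  arena size. Proportional zones shrink the arena polygon about its
  centroid by `sqrt(f)` (the OFT center is the 50% zone, 1012.5 cm² for a
  45 × 45 cm arena); the supported-rear wall band is a true 12.5 cm edge
  offset.
* **Events**: per-frame flags become bouts by merging gaps ≤ 150 ms, then
  dropping bouts < 150 ms.
* **Floating**: thresholding of the local rate of change of the body
  outline ("body area") polygon — static outline = floating.
* **Head dips**: nose off the maze surface while the head centre is on an
  open arm.
* **Rears**: a 2-hidden-layer network (256 and 128 units) over sliding
  15-frame windows of a 22-dimensional position- and orientation-invariant
  skeletal representation (segment lengths, signed joint angles, polygon
  areas, shape ratios), trained from your frame-accurate annotations and
  evaluated by leave-one-video-out cross-validation.
* **Synthetic sessions**: a seeded generator emits DLC-format CSVs of a
  13-keypoint mouse with scripted, ground-truth behavior bouts in any of
  the three arenas — every stage above is testable without video.

See the methods vignette (`vignettes/skeletrack-methods.Rmd`) for the
full model descriptions, parameter meanings and design rationale.

## Worked example

Simulate a 60 s open-field session with three scripted rears, write it as
a DLC-format CSV, and analyze it with the standard OFT configuration:

```r
library(skeletrack)

script <- data.frame(
  behavior = c("supported_rear", "unsupported_rear", "supported_rear"),
  onset_s  = c(12, 31, 47),
  offset_s = c(13.2, 32.4, 48.1))
sc  <- synthetic_scenario("OFT", duration_s = 60,
                          behavior_script = script, seed = 11)
sim <- simulate_session(sc)
write_dlc_tracking(sim$tracking, "oft_demo.csv")

report <- analyze_session("oft_demo.csv", default_session_config("OFT"))
print(report)
#> <session_report> oft_demo (OFT)
#>   duration_s               60
#>   distance_cm              612.795
#>   mean_speed_cm_s          10.2201
#>   px_per_cm                10.0003
#>   fraction_imputed         0.026
#>   time_in_center_s         45.68
#>   visits_center            14
#>   time_in_periphery_s      14.32
#>   visits_periphery         14
#>   time_in_wall_band_s      35.88
#>   visits_wall_band         10
#>   time_in_inner_s          24.12
#>   visits_inner             10
```

The report reads as: the animal covered 6.13 m at a mean speed of
10.2 cm/s; the arena was calibrated at 10.0 px/cm from its corner
landmarks (the generator's true scale is 10); 2.6% of the worst keypoint's
samples were below the likelihood gate and interpolated; occupancy is
split over the 50%-area center vs periphery and, independently, over the
12.5 cm wall band vs the interior. (The generator's random walk has no
wall preference, so these occupancies are geometry checks, not anxiety
measures.)

Rule-based floating detection on a 6-minute forced swim session with
three scripted floating bouts:

```r
script <- data.frame(behavior = "floating",
                     onset_s  = c(60, 150, 240),
                     offset_s = c(75, 170, 262))
sim <- simulate_session(synthetic_scenario("FST", duration_s = 360,
                                           behavior_script = script,
                                           seed = 4))
rep <- analyze_session(sim$tracking, default_session_config("FST"))
print(rep$events$floating)
#> <event_series> floating: 3 events, 56.68 s total @ 25 fps
#>   onset_frame offset_frame onset_s offset_s duration_s
#> 1        1500         1872   60.00    74.88      14.88
#> 2        3752         4250  150.08   170.00      19.92
#> 3        6001         6548  240.04   261.92      21.88
```

All three scripted bouts (52 s total) are recovered with onsets within
two frames.

Training and cross-validating a rear classifier from annotated videos
(here: synthetic, but the same call works on `read_dlc_tracking()` +
`read_annotations()` output):

```r
videos <- lapply(1:6, function(i) {
  sim <- simulate_session(synthetic_scenario("OFT", duration_s = 60, seed = i,
           behavior_script = random_behavior_script(
             c("supported_rear", "unsupported_rear"), 60, 8, seed = i)))
  rep <- analyze_session(sim$tracking, default_session_config("OFT"))
  list(features = extract_skeleton_features(rep$dataset),
       labels   = annotations_to_frame_labels(sim$annotations, 25,
                                              rep$dataset$n_frames))
})
leave_one_video_out(videos, classifier_config(epochs = 20, seed = 1))
```

A command-line front end with `simulate`, `analyze`, `train` and
`predict` subcommands ships in `inst/scripts/skeletrack`.

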