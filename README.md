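# collartrack

Automated monitoring of eating and drinking behaviour in collar-wearing
animals (developed with shelter cats in mind) using printed square fiducial
markers. A unique machine-readable tag on each animal's identification
collar is detected in video; a detection whose center falls inside a
region of interest (ROI) drawn around a resource — a food or water bowl —
is the proxy for resource use. Detections are logged with id, position,
ROI membership, timestamp and frame count, turned into behaviour bouts, and
validated against human-coded ethogram data.

The package is aimed at researchers and animal-care facilities that need
continuous, individual-level behaviour records without per-animal model
training, expensive hardware, or RFID infrastructure.

## What it implements

* **Marker dictionary generation.** Markers are 4×4 grids of black/white
  cells (16-bit code words) inside a black border ring and a white quiet
  zone. Dictionaries are built by seeded rejection sampling under two
  constraints: every code's four 90° rotations are distinct (so orientation
  is always resolvable), and every pair of codes has rotation-invariant
  Hamming distance

  d(a, b) = min over k ∈ {0,1,2,3} of Hamming(a, rot_k(b)) ≥ d_min.

  `render_collar_strip()` tiles one id along a 250 × 25 mm printable
  sticker for attachment to a paper veterinary ID collar.
* **Detection.** Adaptive mean thresholding → connected dark regions →
  convex quadrilateral fitting with sub-pixel corner refinement →
  perspective unwarp → per-cell intensity sampling → match against the
  dictionary over all rotations within a bit-correction budget. A marker is
  only accepted if its black border is intact and its white edge isolates
  the contour.
* **ROI event logging.** Half-open rectangle containment of the detection
  center; sessions run in *post-event* mode (every frame analyzed,
  deterministic logs) or simulated *real-time* mode (newest frame first;
  frames arriving while the detector is busy are dropped and counted).
* **Behaviour analytics.** Binary presence series per subject and ROI at
  frame or second resolution; bout segmentation under the ethogram rule
  that ≥ 60 s (1800 frames at 30 fps) of non-engagement starts a new
  event; daily/hourly summaries.
* **Validation statistics.** Shrout–Fleiss intraclass correlation
  coefficients — ICC(1,1), ICC(2,1), ICC(3,1) — computed from two-way ANOVA
  mean squares with F tests and confidence intervals, and Cohen's kappa
  κ = (p_o − p_e)/(1 − p_e) with a large-sample z test, for agreement
  between tracker output and human-coded behaviour.
* **Synthetic scenes.** A seeded generator that warps markers onto textured
  backgrounds at known poses with noise, blur, illumination change and
  "fur" occlusion, plus a simulated human coder with controllable miss,
  false-alarm and boundary-jitter rates — so the full pipeline is testable
  with exact ground truth and no recordings.

## Worked example

```r
library(collartrack)

dict <- generate_dictionary(16, grid_size = 4, min_distance = 1, seed = 7)
dict
#> Marker dictionary: 16 codes, 4x4 grid (16 bits), min rotation-invariant distance 1, seed 7

rois <- list(roi(0, "water", 5, 30, 55, 60),
             roi(1, "food", 105, 30, 55, 60))

# synthetic 120-frame clip: subject 10 at the food bowl in 30-frame episodes
visible <- rep(rep(c(TRUE, FALSE), each = 30), length.out = 120)
scene <- generate_scene(scene_spec(
  width = 165, height = 120, n_frames = 120, fps = 30, dict = dict,
  rois = rois,
  subjects = list(subject_track(10, 120, x = 132, y = 60, side = 44,
                                visible = visible, using = visible)),
  seed = 20))

res <- run_post_event(scene, dict, rois, fps = 30)
res$report
#> Session (post_event): 120 frames total, 120 analyzed, 0 dropped
head(res$log, 3)
#>   frame  timestamp id   x  y rois
#> 1     0 0.00000000 10 132 60    1
#> 2     1 0.03333333 10 132 60    1
#> 3     2 0.06666667 10 132 60    1

ser <- presence_series(res$log, subject = 10, roi = 1, n_frames = 120)
segment_bouts(ser, gap_threshold = 1800)
#>   subject roi start end duration presence
#> 1      10   1     0  89       90       60
```

The log records a detection in the food ROI on exactly the 60 frames the
marker is visible there. The 30-frame absences are far below the 1800-frame
bout threshold, so the three visible episodes merge into a single feeding
bout spanning frames 0–89 (90 frames of bout, 60 of actual presence).

Validation against a simulated human coder with a 5% miss rate and 1%
false-alarm rate:

```r
coding <- simulate_coder(truth_series(scene, 10, "using", roi = 1),
                         miss_rate = 0.05, false_alarm_rate = 0.01, seed = 2)
cohen_kappa(align_series(ser, coding))
#> kappa = 0.950 [0.894, 1.000], z = 10.420, p = 2.01e-25, n = 120
```

A command-line interface wrapping the same functions is installed at
`inst/cli/collartrack` with subcommands `markers`, `track`, `analyze`,
`validate` and `simulate` (run it without arguments for usage).

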