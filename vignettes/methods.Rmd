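---
title: "Methods: marker-based behaviour tracking and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based behaviour tracking and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collartrack)
```

## The measurement model

collartrack estimates *resource use* — eating at a food bowl, drinking at a
water bowl — for individually identifiable collar-wearing animals. The
chain of proxies is explicit, and each link is a place where error can
enter:

1. a printed fiducial marker identifies the animal (misses occur when the
   code or its white edge is occluded, e.g. by a long coat);
2. the marker-center position stands in for the animal's head position
   (the collar sits at the neck, so this is a good proxy for head-at-bowl
   postures under an overhead camera);
3. presence of that center inside a fixed rectangle around the resource
   stands in for using the resource (an animal can occupy the rectangle
   without eating — presence without use — which no ROI scheme can
   distinguish).

The package therefore treats agreement with human-coded behaviour as the
measure of validity, not detection accuracy alone, and ships the agreement
statistics (ICC, Cohen's kappa) as first-class outputs.

## Marker dictionary

Markers are `grid_size` × `grid_size` binary cell grids (default 4 × 4,
16-bit code words; bit 1 = white cell) surrounded by one ring of black
border cells and a white quiet zone. Dictionaries are drawn by seeded
rejection sampling with two acceptance rules:

* *orientation resolvability* — all four 90° rotations of a code must be
  distinct, otherwise corner order (hence marker orientation) would be
  ambiguous at detection time;
* *separation* — every pair of codes must have rotation-invariant Hamming
  distance at least `min_distance`.

The default `min_distance` is 1 for a 16-marker dictionary: 16 bits leave
ample room for 16 distinct codes, and the bit-correction budget
`floor((min_distance - 1)/2)` is then 0, i.e. exact matching. Users who
expect heavy degradation can regenerate with a larger floor and gain error
correction at the cost of longer sampling. The generator fails with a clear
message after a bounded number of draws when the constraint set is
infeasible (e.g. many markers on a small grid with a large distance floor).

The bit patterns themselves are arbitrary; any seed yields an equally valid
dictionary, which is why the dictionary file records the seed, grid size,
distance floor and integer code words, and why no particular pattern set is
distributed.

## Detection pipeline and its tunables

`detect_markers()` runs four stages. All tunables live in
`detector_params()`; defaults are chosen for overhead indoor footage where
a marker spans roughly 40–100 px.

* **Adaptive mean threshold** (`adaptive_window`, default 15 px): each
  pixel is compared with the mean of a sliding window, computed by an
  integral image with edge-clipped windows. No offset constant is
  subtracted, which makes the binarization exactly invariant under affine
  intensity rescaling with positive gain — illumination changes shift what
  the threshold sees but not the result. A window larger than the frame
  falls back to a global mean threshold with a warning.
* **Quad extraction** (`min_area_frac` 1e-4, `max_area_frac` 0.95,
  `approx_tol_frac` 0.03, `aspect_max` 4, `min_side` 8 px): connected dark
  regions are traced to outer contours; each contour's convex hull is
  reduced to four vertices by iteratively removing the vertex whose loss
  changes area least; the candidate survives only if the whole contour
  stays within `max(1.5, approx_tol_frac × perimeter)` pixels of the quad
  boundary. Below `min_side` pixels per edge a 6-cell-wide code cannot be
  sampled at one pixel per cell, so smaller blobs are dropped before any
  fitting. Corners are refined to sub-pixel precision by total-least-squares
  lines fitted to the contour points backing each edge, pushed half a pixel
  outward (contour points are centers of boundary pixels, half a pixel
  inside the true edge), and intersected.
* **Decoding** (`cell_samples` 3, `min_contrast` 0.1): the quad is
  unwarped by an exact four-point homography and every cell of the
  (grid + 2)² layout is sampled on the *grayscale* frame over a 3 × 3 grid
  covering its central 50%. Bits are read against the midpoint of the
  sampled intensity range rather than from the binarized image, because
  adaptive thresholding hollows out solid regions larger than its window.
  Candidates are rejected when the sampled range is below `min_contrast`
  (a featureless dark blob carries no code), when any border cell reads
  white, or when the best dictionary match is not unique or exceeds the
  correction budget.
* **Post-processing**: overlapping detections of one physical marker keep
  the lowest-Hamming, then largest-area quad; results are sorted by id,
  then center y, then x, so output order is deterministic.

Coordinates are pixels with the origin at the top-left corner, x rightward,
y downward, sub-pixel floats; pixel (row r, col c) covers
[c−1, c) × [r−1, r). The logged (x, y) is the *center* (mean of the four
corners). Which point the original deployment logged is not documented
anywhere we could find, so the center was chosen as the only
rotation-neutral option and is stated here for comparability.

## ROIs and sessions

ROIs are static, axis-aligned rectangles (the deployment constraint that
encourages perpendicular camera placement). Containment is half-open —
left/top edges in, right/bottom edges out — so adjacent rectangles tile
without double counting; the convention is arbitrary but must be fixed, and
is tested. Containment is evaluated on the detection center only, matching
the one-point-per-detection log schema; users should size ROIs so a
head-at-bowl marker center falls inside. `validate_layout()` warns about
overlapping or close ROI pairs before a session, because resources placed
too close are the dominant deployment failure: one detection then carries
two ROI indices, and `assign_rois()` deliberately reports all of them
rather than guessing.

Post-event sessions analyze every frame in order and are pure functions of
the input and config (logs are written with fixed number formatting so
repeated runs are byte-identical). Real-time sessions are modelled as a
discrete-event simulation: the detector always picks up the newest arrived
frame, and frames arriving while it is busy are dropped and counted, so
`frames_analyzed + frames_dropped = frames_total` holds exactly and
"temporal priority" is implemented literally. Real-world wall-clock
behaviour depends on hardware; the simulation makes the drop policy and its
accounting testable. Log rows are flushed incrementally in real-time mode,
so an interrupted stream (the field failure mode is power loss) leaves a
valid partial log and a report flagged truncated. Timestamps are media time
(frame/fps) in post-event mode and clock seconds in real-time mode; the
CSV dialect (`frame,timestamp,id,x,y,rois`, semicolon-joined ROI indices)
is declared, not inherited, and enables byte-exact tests.

## Bouts

Presence series are binary per frame (or per second, by any-presence
binning). Bout segmentation merges presence runs separated by gaps shorter
than the threshold; a gap **≥** threshold starts a new bout. The ethogram
states "around 1 min (60 s or 1800 frames)", so a strict convention was
required: this package uses gap ≥ threshold, measured from presence-end to
presence-start. The default is 1800 frames at frame resolution (30 fps) and
60 s at second resolution. Bout duration is end − start + 1 units,
counting merged interior gaps; the `presence` column keeps the actual
presence so segmentation provably conserves it. Daily/hourly summaries
split straddling bouts at bin boundaries with duration conserved.

## Agreement statistics

Tracker output and human codings are aligned (`align_series()`) by
resampling frame series to seconds with any-presence binning when needed
and trimming to the overlapping interval. ICCs are computed from two-way
ANOVA mean squares with the classical single-measurement forms; the default
is ICC(2,1) — two-way random effects, absolute agreement — because a
method-vs-human comparison treats both "raters" as random and cares about
absolute agreement, but the published analysis does not state its form, so
`sweep_icc_forms()` reports all three side by side and flags the closest
match to a reference value instead of guessing intent. Cohen's kappa is
reported alongside every ICC for the same reason: the source material mixes
the two labels. Degenerate inputs (constant series, expected agreement 1)
return reports flagged `undefined` rather than silent numbers.
`reproduce_published_agreement()` accepts the study's data files when a
user has them, and degrades to an explicit per-target "unmatched, files
not available" report when they are absent — those files are not
redistributable with this package.

## What the synthetic scenes do and do not show

`generate_scene()` renders markers through exact per-frame homographies
(in-plane rotation plus out-of-plane tilt under a perspective camera with
focal length 4 × marker side) onto a seeded textured background, then
applies illumination gain/offset, Gaussian blur, sensor noise, and opaque
soft-edged "fur" ellipses for occlusion. Ground truth records true corners,
centers, ROI membership and the latent using-vs-present state per frame,
and the per-frame seeding (`seed + 7919 × frame`) makes lazy and eager
generation bit-identical. The simulated coder corrupts ground-truth series
with independent misses, false alarms and bout-boundary jitter, which gives
closed-form expected kappa values for parameter-recovery tests.

These scenes validate geometry, decoding, logging, segmentation and the
statistics. They do not contain animals: no deformable fur except as
ellipses, no motion blur, no rolling shutter, no compression artifacts, no
shadows. Passing tests therefore demonstrate that the algorithmic chain is
correct and calibrated, not that any particular camera installation will
reach a given agreement level; that remains a property of marker size on
screen, lighting, and resource placement.

Problem sizes used by the test suite were chosen to exercise every
contract at full fidelity while staying desk-scale: 120–165 px frames with
40–56 px markers (the detector's working regime starts near 40 px), a
3000-frame session for the accounting contracts, and n = 10⁴ units for the
Monte-Carlo statistics.

## Known limitations

* Rectangular static ROIs only; marker-anchored dynamic ROIs are a named
  future extension.
* No 3D pose, lens-distortion calibration, or cross-frame motion tracking;
  each frame is independent.
* Corner localization degrades beyond ~20° of tilt (id recovery holds to
  30°); the half-pixel contour offset model assumes near-fronto-parallel
  edges.
* Presence-without-use is by construction invisible to the detector and
  shows up only as depressed agreement with human coding.
* Video container decoding is out of scope: sessions consume frame
  directories (PNG), in-memory frames, synthetic scenes, or any
  user-supplied `function(i)` frame source.
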