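---
title: "Tracking surgical instruments and quantifying surgical skill with sitrack"
author: "sitrack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking surgical instruments and quantifying surgical skill with sitrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitrack)
```

## The problem

Surgical skill in robotic surgery is conventionally rated by human experts
with structured rubrics (OSATS for open/laparoscopic technique, GEARS for
robotic technique; three items, each scored 1–5). These ratings are
subjective and require an expert to watch long recordings. Because most of
what the rubrics reward is visible in how the *instruments* move, an
automatic alternative is to track the instruments in the endoscopic video,
convert their tip trajectories to metric units, summarize them as motion
metrics, and classify the operator as novice, skilled or expert.

Doing that from video alone raises two specific difficulties that this
package is organized around:

1. **Occlusion and identity.** Instruments cross, leave the view and
   re-enter; their shafts look alike. A per-frame detector cannot say *which*
   instrument it found, so identity must come from temporal association
   (tracking) plus appearance re-identification.
2. **Confounded motion.** The robot console overlays arm-status indicators
   (which of the two driven instrument arms is active) and a camera-arm
   indicator (the laparoscope is being moved). An instrument that merely sits
   in the view while the camera pans *appears* to move; an inactive
   instrument parked in the view must not contribute to motion metrics.
   Indicator recognition gates the trajectory accordingly.

## Pipeline

`runPipeline()` executes, per frame: detection → non-maximum suppression →
tracking → cascaded re-identification → indicator recognition → tip
localization, then once per video: metric calibration → trajectory gating →
motion metrics.

### Detection

Detection is a pluggable interface producing class-free candidates, each a
bounding box, a binary mask and a confidence. Two providers ship with the
package: a ground-truth oracle with a parametric corruption model
(translation jitter, misses, Poisson false positives, occlusion merging) for
controlled experiments, and `colorSegment()`, a classical channel-ratio
segmenter (tissue is strongly red-dominant; instruments are not) with
connected-component labelling. Detections deliberately carry no instrument
class: partially visible instruments cannot be typed reliably from one
frame, so recognition is framed as binary foreground/background and identity
is left to the tracker and re-identification stages.

### Tracking

`trackerStep()` is a SORT-style tracker-by-detection. Each track carries a
constant-velocity Kalman filter over `(cx, cy, aspect, h)` with process and
measurement noise scaled to box height (weights 1/20 and 1/160), so the
behavior is scale-invariant. Association runs as a matching cascade:
recently updated confirmed tracks are matched first, with a combined cost
`lambda * mahalanobis + (1 - lambda) * appearance cosine distance`
(`lambda = 0.02`, appearance-dominant) gated at the chi-square 0.95 quantile
with 4 degrees of freedom (9.4877). Remaining tracks get an IOU-only pass
(gate 0.3) that considers the *last observed* box as well as the prediction;
this pass exists precisely for motion-model failures (abrupt accelerations,
masks shrinking at the border during withdrawal), so it must not rely solely
on the failed prediction. The Hungarian algorithm (`solveAssignment()`, an
O(n³) shortest-augmenting-path implementation, exact) optimizes each pass.

Tracks confirm after 3 consecutive hits and die after 30 unmatched frames;
both are configurable. At most three instrument tracks may be confirmed at
once — the robotic-surgery view never shows more — and a confirmation that
would exceed the cap is denied without resetting the hit count, so the
blocked track confirms the moment a slot frees.

### Re-identification

Identity labels survive exits and crossings through a two-stage cascade.
The offline stage is an appearance gallery: up to 50 exemplar descriptors
per identity (at most three identities), matched by minimum cosine distance.
The descriptor is a classical stand-in for a learned embedding, behind the
same interface: a 3×3 spatial grid over the box, each cell contributing a
joint 8-hue × 4-saturation histogram plus a 9-bin gradient-orientation
histogram, L2-normalized, computed over mask pixels only so that background
inside the box of a diagonal shaft does not dilute it. Gallery exemplars are
added only from high-confidence, unoccluded associations.

When the offline stage predicts an identity *change* (its rank-1 identity
differs from the track's incumbent label), the online stage arbitrates: a
bag-of-visual-words model is fit on local patches from the previous ten
frames (k-means vocabulary, k = 32, fixed seed) and votes by word-histogram
similarity. The final identity is the vote when it agrees with either
candidate, else the incumbent is retained; appearance ties (cosine margin
under 0.02) retain the incumbent outright, since motion continuity is then
the only information. Degenerate windows fall back to the offline proposal.
At most one live confirmed track may hold an identity; a conflicting *lost*
owner is treated as a stale hypothesis of the same instrument and yields its
label, while a conflicting confirmed owner keeps it only if its gallery
distance is smaller.

`reidBenchmark()` measures the three routes (offline-only, online-only,
combined cascade) as rank-1 cumulative matching accuracy on a seeded
gallery/query benchmark with re-entry queries (partial insertion, pixel
noise, global brightness shift) and crossing queries (the instruments have
just separated; a band of another shaft corrupted the view). The benchmark
renders instruments with *identical* hue — real instruments look alike, so
identity rests on shaft orientation and texture — which is what separates
the fine-grained offline descriptor from the deliberately coarse online
words (per-patch mean color and gray s.d.). The standalone online baseline
works on box crops, as a generic retrieval method would; the cascade's
stage 2 is allowed the mask because it runs inside the pipeline where
segmentation exists. The incumbent supplied to the cascade is the tracker's
motion-continuity hypothesis; this package's tracker carries identities
through crossings reliably, so the benchmark defaults to a correct
incumbent (`swapProb = 0`), and the fusion rule then can only improve on the
offline stage. The expected ordering, combined ≥ offline-only ≥ online-only,
is asserted by the test suite.

### Indicators and gating

Indicator templates are stored in advance with their fixed anchor regions
and matched by maximum normalized cross-correlation (threshold 0.8; constant
windows score 0). `gateTrajectory()` then adds validity flags without
touching positions: samples on camera-moving frames are invalid for motion
(their displacement is excluded rather than compensated — the simpler of the
two options, and exact when instruments hold still during camera moves),
and identities whose arm is inactive are flagged inactive. The arm of an
identity is inferred from the median x position of its trajectory (arm
indicators sit on the side their instrument works from); the mapping can be
overridden. Camera-moving frames still count toward laparoscopy-usage
duration.

### Tips and calibration

The trajectory must follow the instrument *tip*, not the box center. When
the mask touches an image border (the shaft always enters from outside the
view), the tip is the mask pixel farthest from the centroid of the
border-contact pixels, with a deterministic tie-break (smallest y, then x);
interior masks fall back to the extreme pixel along the major principal
axis on the end with the smaller perpendicular width. This geometric rule is
exactly translation-equivariant, which is what makes the noise-propagation
analysis below clean.

Pixels convert to millimetres through the known 8 mm shaft width: the
on-screen width is the median perpendicular extent of an elongated mask
along its principal axis, aggregated over the first ten qualifying masks and
rounded to the nearest pixel (screen widths are integer pixel counts). The
calibration is measured once and held for the whole video; zoom changes
during a video are a documented error source.

## Motion metrics

Nine metrics summarize one operation (units in parentheses; all computed
from the gated, calibrated trajectory):

* **time to completion** (s) — analyzed segment length / fps;
* **instruments out of view** (count) — maximal intervals during which an
  active arm has no confirmed in-view instrument on its side;
* **instrument collisions** (count) — onset events of mask overlap between
  distinct confirmed instruments;
* **economy of motion** (mm) — total tip path length over consecutive
  valid-motion samples, summed over instruments;
* **average speed** (mm/s) — economy over total valid-motion duration;
* **number of movements** (count) — maximal runs of the smoothed speed
  series (moving average, window 5) above 2 mm/s lasting at least 0.2 s;
* **economic factor** (unitless) — mean episode straightness, net
  displacement over path length (this package's stated interpretation of an
  otherwise loosely defined quantity; a zero-net loop scores 0 and is
  included in the mean);
* **instrument changes** (count) — paired events where one identity leaves
  the view for good and a *different* identity arrives within a short window
  (default: absences of at least 30 frames qualify, arrival within 60 frames
  after the departure). A literal per-frame membership count would score a
  single swap twice, and activity toggles without a visibility change are
  arm usage, not instrument changes;
* **laparoscopy usage** (count and s) — maximal camera-moving intervals.

For modelling, `normalizeMetrics()` applies two stages: duration-dependent
metrics are divided by the operation time (counts become per-minute rates,
economy becomes mm/s, laparoscopy duration a fraction; time itself, average
speed and the economic factor are intensive and stay raw), then every column
is z-scored across the cohort. The stored transform reapplies both stages
to new subjects; zero-variance columns standardize to zero with a warning.

## Skill models

`trainSkillModel()` fits a multinomial linear classifier, a Gaussian-kernel
SVM (tuned regularization cost in {0.1, 1, 10, 100}) or a Gini random forest
(trees in {50, 100, 200, 500} × depth in {2, 3, 5, unbounded}), selected by
stratified 5-fold cross-validated accuracy. Class imbalance is handled by
SMOTE — synthetic minority samples interpolated uniformly on segments
between a minority point and one of its k nearest same-class neighbours —
applied *inside each training fold only*: balancing before the split would
leak synthetic copies of validation points into training. The tuned model
is refit on all (balanced) training data. `featureImportance()` reports the
forest's mean Gini impurity decrease, normalized to sum one.

## The synthetic scene simulator

Real surgical videos cannot ship with a package, so every stage is testable
against `generateScene()`: 1–3 rigid elongated instruments rendered as
flat-shaded capsule shafts (half-open rasterization band, so an
axis-aligned shaft is exactly `shaftWidthPx` pixels wide and the metric
calibration is recoverable) with a tapered metallic tip wedge, pivoting
about fixed trocar-like points outside the view; a seeded background
texture; scheduled exit/re-entry events, crossings, camera translations
(out-and-back, flagged by the camera indicator) and an active-arm schedule
rendered as indicator overlays. Ground truth records per-frame masks, tight
boxes, tip pixels, visibility and the schedules; coordinates are 0-based
pixel centers with half-open boxes. Everything derives from one seed, and
generation is byte-reproducible.

Choices worth knowing:

* The ground-truth tip is defined as the mask pixel farthest from the exact
  shaft-entry point — renderer-privileged geometry, deliberately not the
  same rule as `detectTip()`, so perfect zero-noise agreement between the
  two is a genuine cross-check rather than a tautology.
* Exit events retract the tip along the shaft with easing (the last visible
  steps are slow), pull it out, dwell, snap back to a near-border hold point
  where it rests a few frames, then rejoin the path. The hold gives any
  tracker's confirmation logic a stationary target, so confirmation lag
  costs no path length; the scene remains hard (the track is genuinely lost
  and must be re-identified) without being unmeasurable.
* Detection masks are amodal: an occluded instrument still yields its full
  silhouette, mirroring an idealized instance-segmentation stage. Occlusion
  merging is available as an explicit corruption.
* Under per-axis Gaussian mask jitter of σ px the detected tip error is the
  jitter itself (translation equivariance), so the RMSE converges to
  σ·√2·mmPerPx plus a small integer-rounding contribution (variance 1/12
  px² per axis) — the package's noise-calibration check.

The cohort generator `generateSkillCohort()` emulates the three surgeon
groups at the trajectory level: movement episodes with class-conditional
speed, path inefficiency (curved excursions) and pause structure until a
fixed productive task length is reached, plus Poisson-scheduled
out-of-view episodes, collisions, instrument changes and laparoscope moves.
Class means are ordered expert ≤ skilled ≤ novice in inefficiency,
out-of-view rate and collision rate (enforced), with a 12% between-subject
coefficient of variation. The published work does not quantify how strongly
its surgeon groups differ, so these effect sizes are this package's own
defaults, chosen once so that classes are separable but overlapping —
held-out accuracy of the tuned forest sits around 0.75–1.0 on 12 held-out
subjects, not at ceiling for every split. Pauses shorter than one second are
not emitted: they are invisible to a 5-sample smoothed speed threshold and
would blur the episode structure the economic factor depends on.

## What passing these tests does and does not show

The simulator provides geometric fidelity (masks, occlusion, exits, overlay
indicators, metric scale) but not photometric realism: no specularity,
smoke, blood, tissue deformation or motion blur, and its texture statistics
are far simpler than endoscopic video. Zero-noise perfection and correct
noise propagation demonstrate that the *algorithmic* chain — association,
identity logic, gating, geometry, calibration, statistics — is correct;
they say nothing about a real detector's error distribution. Published
headline numbers on real surgical video (tip RMSE near 3.5 mm, AUC 0.7–0.86
at 1–5 mm, rank-1 re-identification near 90%, 83% skill accuracy on a
40/12 split) depend on those videos and are not reproducible at desk scale;
the package instead pins down every property that *is* checkable without
them, at stated problem sizes (500-frame three-instrument scenes for the
end-to-end check, 10⁴ samples for noise calibration, 40 re-identification
queries, 52-subject cohorts).

Known limitations, mirrored from the underlying approach: errors accumulate
over very long videos; a zoom change mid-video breaks the single
calibration; depth is absent (2-D tip positions only); and re-identification
mistakes propagate into the metrics — a manual correction pass is the
operational remedy, out of scope here.

## Worked example

```{r example, eval = FALSE}
scene <- randomScene(nInstruments = 3, nFrames = 500, seed = 2)
res <- runPipeline(scene)
res$metrics
evaluateTracking(res, scene)
```
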