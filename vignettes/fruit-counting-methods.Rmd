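---
title: "Counting orchard fruit by tracking detections: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting orchard fruit by tracking detections: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peartrack)
```

## The problem

Estimating fruit yield from video is a tracking-by-detection problem. A
detector proposes bounding boxes frame by frame; because detectors flicker
(drop a visible fruit for a few frames), double-fire, and miss occluded
fruit, raw detection counts are not fruit counts. A multi-object tracker
links detections into identity-persistent tracks, and the count is then read
off the tracks in one of two ways:

* **unique-ID counting** — the number of distinct confirmed track
  identifiers emitted over the video; sensitive (every tracked fruit is
  counted) but inflated by identity fragmentation;
* **ROI-line counting** — the number of tracks whose centroid crosses a
  horizontal region-of-interest line (by default at 50% of the frame
  height); restrictive (a fruit must be tracked *while it passes the
  line*), so it suppresses false positives but misses fruit whose track
  starts only after the line.

A third variant counts unique IDs whose track carried detections on at
least 80% of their lifespan, a remedy for flicker-born fragment tracks.
`peartrack` implements all three, the tracker beneath them, the detection
and counting evaluation metrics, and a synthetic orchard-pass simulator
that makes every stage testable without any video data.

## The tracker

The tracker follows the online simple-realtime-tracking design with a deep
association metric: a constant-velocity Kalman filter on the state
$(c_x, c_y, a, h, \dot c_x, \dot c_y, \dot a, \dot h)$, where $a$ is the
box aspect ratio and $h$ its height; Mahalanobis-gated association of
predicted tracks to detections solved as a linear assignment problem
(Hungarian algorithm, implemented in compiled code and property-tested
against exhaustive enumeration); a matching cascade that prefers recently
updated tracks; and a tentative/confirmed/deleted lifecycle
(`n_init = 3` consecutive hits to confirm, `max_age = 30` coasted frames
before deletion). Process and measurement noise scale with box height, and
the gate is the 0.95 chi-square quantile at 4 degrees of freedom. All of
these are configurable through `tracker_config()`.

Association cost is pluggable: `1 - IoU` of the predicted and detected
boxes, the minimum cosine distance between the detection's appearance
embedding and the track's bounded gallery (100 vectors, FIFO), or a convex
combination (`appearance_weight`, default 0.5). Embeddings are inputs —
read from a sidecar file or produced by the simulator — never computed by a
network inside this package; when they are absent the combined mode
degrades to pure IoU.

Three deliberate deviations from the pedestrian-tracking conventions of the
cited family, all motivated by geometry rather than tuning:

1. **Aspect noise.** Pedestrian trackers treat the box aspect ratio as
   nearly constant (process std $10^{-2}$). Fruit boxes here are clipped
   while entering and leaving through the frame edges, so the *measured*
   aspect swings by an order of magnitude within a few frames. A newborn
   track therefore starts with an uncertain aspect (init std 1) and keeps
   enough aspect process noise (std 0.05 per frame) to follow the clipping
   dynamics. Without this, every fruit acquires a second identity at the
   frame edge.
2. **Gating by stage.** The IoU association stage is gated by the IoU cost
   ceiling only. Applying the Mahalanobis gate there orphans newborn tracks
   whose box is still growing into view (the height innovation is many
   sigmas while the box is clipped).
3. **Appearance-gated cascade.** When embeddings are available, cascade
   admissibility is the appearance budget (`max_appearance_cost`, default
   cosine distance 0.25) instead of the Mahalanobis gate; motion still
   shapes the combined cost. The constant-velocity model is transiently
   wrong exactly when a flicker gap spans the frame-entry transition (the
   centroid velocity doubles when the box un-clips), and those are the
   recaptures the appearance signal exists to make. With weakly
   discriminative embeddings the budget should be tightened, or
   `cost_mode = "iou"` used, which restores the classical
   Mahalanobis-gated behavior.

Track histories are contiguous: coasted frames carry the predicted box
flagged `had_detection = FALSE`, which lets the ROI-line counter bridge
flicker at the line. When a track dies, trailing predicted-only frames are
truncated, so a lifespan runs from the first to the last *detected* frame —
otherwise every track would end with `max_age` phantom frames and the
lifespan filter would reject perfect tracks.

## Evaluation metrics

Detection evaluation follows the Pascal-VOC protocol: a detection above the
confidence threshold (default 0.25) is a true positive when its IoU with an
unclaimed ground-truth box is at least 0.5 (defaults; both configurable),
matched greedily in descending confidence with ties broken by (frame, left,
top); suppressed low-confidence detections are neither TP nor FP but leave
their object unclaimed (a false negative). Average precision is the 11-point
interpolated form, $\mathrm{AP} = \frac{1}{11}\sum_{r}
\max\{P(\tilde R): \tilde R \ge r\}$, computed from a full confidence sweep.
The greedy TP count is property-tested against a brute-force
maximum-cardinality matching oracle.

Counting evaluation uses the CLEAR-MOT subset appropriate for static
objects viewed from a moving camera: counted track IDs are assigned to
ground-truth objects by greedy descending mean co-visible IoU (admissible
at 0.3, configurable), giving counting TP/FP/FN, from which
$R$, $P$, $F_1$ and $\mathrm{MOTA} = 1 - (FN + FP +
\mathrm{mismatches})/\mathrm{total}$ follow, with mismatches fixed at 0
because the fruit do not move. Two FP-rate conventions exist in the wild;
the default is $FP/\mathrm{total}$, under which
$\mathrm{MOTA} = 1 - FN_\mathrm{rate} - FP_\mathrm{rate}$ holds exactly —
the convention consistent with published comparison tables of this metric
family — while $1 - P$ is selectable. The false-negative breakdown
classifies each missed object as never detected, detected only past the
line, first detected within a ±5% band around the line, or other.

## The simulator

`generate_scene()` emulates a camera moving at constant speed along a row
of static fruit, filmed portrait so the image content moves vertically and
every fruit crosses a horizontal line. Fruits are placed uniformly along a
world strip and across the frame width; a fruit is visible while its box
intersects the viewport and visible boxes are clipped to the frame.
Defaults — 50 fruit, 1080×1920 frames, 20 px/frame camera speed, 60–140 px
boxes, a 4000 px strip — give ≈300-frame passes with ≈25 fruit in view at
once and each fruit visible for ≈100 frames, the regime of a hand-held
orchard pass. These sizes are also what the test-suite and the acceptance
script run, chosen so a full pipeline pass takes seconds on one CPU.

`corrupt_detections()` degrades the ideal stream with the failure modes
that matter downstream, each drawn from its own seeded substream:

* **flicker** — each fruit-frame detection dropped independently with
  probability `p_miss`. One uniform is drawn per fruit-frame and compared
  against `p_miss`, so runs sharing a corruption seed are monotonically
  coupled across `p_miss` values: raising the rate only removes detections.
* **occlusion episodes** — Poisson(`occlusion_rate`) contiguous dropouts
  per fruit, 10–45 frames by default. Episodes longer than the tracker's
  `max_age` are what fragment tracks; a fragmentation that spans a fruit's
  line-crossing produces an ROI-line miss, while the unique-ID method
  records the same fruit twice (a false positive instead of a false
  negative). This asymmetry is the qualitative signature the trend tests
  check: with occlusions held fixed under coupled seeds, increasing
  flicker raises the ROI-line FN rate strictly while the unique-ID FN rate
  stays near zero.
* **localization jitter** — Gaussian center noise (`jitter_sigma`, 2 px
  default) and relative log-size noise `jitter_sigma / size`, capped so
  sub-pixel clipped slivers cannot explode.
* **false positives** — Poisson(`fp_rate`) spurious boxes per frame with
  their own confidence model and fresh random embeddings.
* **appearance** — each fruit owns a fixed random unit embedding
  (128-dimensional, the convention of CNN re-identification embeddings;
  much lower dimensions make random vectors collide in cosine distance);
  detections get the base vector plus noise of RMS norm `embedding_noise`
  (0.1), renormalized.

What the simulator does **not** model: illumination, perspective and
parallax (fruit at different depths move at the same image speed),
appearance drift with viewpoint, correlated detector failures, and fruit
motion. Passing tests on this simulator therefore demonstrate the
correctness of the tracking/counting/evaluation machinery and its
qualitative failure modes, not detector-level performance on real orchard
video.

## Training-methodology utilities

The package also ships the surrounding training utilities as pure
functions. The learning-rate schedule ramps linearly to `lr0` over the
first 1000 iterations and is then piecewise constant, multiplied by
`d = 0.1` immediately *after* each step iteration (4800 and 5400 by
default, 6000 iterations total): the update rule decays the rate at the
step, so the new rate first applies on the following iteration.
`split_dataset()` performs the four-way 70:10:10:10 split with
largest-remainder rounding (ties to the earlier partition), shuffles at the
level of original-image groups so augmented derivatives never straddle
partitions, restricts high-resolution items to train/train-val and phone
items to val/test, and treats a source shortfall as an explicit error
rather than silently backfilling. `kmeans_anchors()` clusters box
dimensions under the `1 - IoU` anchor distance with seeded k-means++
initialization; centers are updated to the cluster medoid (the member
minimizing summed distance), which — unlike coordinate means under this
non-Euclidean distance — guarantees the mean cost never increases, an
invariant the test suite asserts. `error_gap_report()` encodes the staged
reading of the four-way split's APs (bias, overfit, data mismatch,
validation overfit) with a 2-percentage-point tolerance; the bias stage
needs a user-supplied target AP and is reported `NA` without one.

## Numerical and degenerate-input choices

* The Kalman update uses the Joseph form and the predict step floors the
  height/aspect state at small positive values: long coast/update cycles
  otherwise lose positive definiteness.
* Assignment forbids pairs at/above the sentinel by big-M substitution, so
  feasible matches are maximized before cost is minimized; matrices up to
  6×6 are checked against exhaustive enumeration.
* A centroid exactly on the ROI line counts as crossing on the next
  off-line frame; a track is counted at most once regardless of
  re-crossings; "at least 80% of lifespan" includes the boundary.
* Empty cases are defined, not errors: empty streams yield empty track
  sets, empty scenes evaluate to zero-count records, AP with zero ground
  truth is 0 with a warning.
* MOT files are 1-based on disk and 0-based in memory; writers emit a
  fixed decimal format so write–read–write round-trips are byte-identical,
  and the pipeline re-reads what it writes so staged and single-shot runs
  produce identical artifacts.

## Known limitations

The tracker is pure R with a compiled assignment core; it processes a
300-frame, 25-objects-per-frame pass in a few seconds, which is adequate
for analysis but not a real-time deployment. Appearance-gated cascading
assumes embeddings that separate object identities; with weak embeddings
the classical IoU mode should be preferred. The counting evaluator matches
tracks to objects by mean co-visible IoU, which is the standard practice
but can under-credit a counter when tracks are heavily fragmented.
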