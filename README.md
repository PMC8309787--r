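# peartrack

Counting fruit in orchard video from per-frame bounding-box detections.

Hand counting pear yield is slow, and raw per-frame detection counts are
not fruit counts: detectors flicker, double-fire and lose occluded fruit.
`peartrack` is a detector-agnostic R toolkit that turns a detection stream
(MOT-challenge `det.txt` or YOLO/Darknet per-frame text files) into a fruit
count by tracking-by-detection, and evaluates both the detections and the
counts against ground truth. It is aimed at agricultural image-analysis
work where the detector lives elsewhere (a CNN, a cloud service) and the
tracking, counting and evaluation need to be reproducible and testable.

## What is inside

* **Tracker** — an online multi-object tracker in the
  SORT-with-appearance mold: constant-velocity Kalman filter on
  (cx, cy, aspect, height), Hungarian assignment (compiled, tested against
  exhaustive enumeration) over IoU / appearance-embedding / combined costs
  with Mahalanobis or appearance gating, matching cascade, and a
  tentative → confirmed → deleted lifecycle.
* **Counters** — unique track-ID counting, horizontal ROI-line crossing
  counting (line at 50% frame height by default), and a lifespan-coverage
  filtered variant (counts IDs detected on ≥ 80% of their lifespan).
* **Detection metrics** — Pascal-VOC protocol: IoU ≥ 0.5 TP matching at a
  0.25 confidence threshold, P/R/F1/FNR/FPR, average IoU, 11-point
  interpolated AP.
* **Counting metrics** — CLEAR-MOT subset with mismatches = 0 for static
  fruit: `R`, `P`, `F1`, and `MOTA = 1 − (FN + FP + mismatches)/total`,
  plus a false-negative breakdown by failure mode (never detected /
  detected only past the line / detected near the line / other).
* **Simulator** — a synthetic orchard pass (moving camera over static
  fruit) with a corruption model: flicker, occlusion episodes,
  localization jitter, Poisson false positives, confidence noise and
  per-fruit appearance embeddings; every downstream stage is testable
  without video data.
* **Training utilities** — multi-step learning-rate decay with linear
  warmup, the four-way 70:10:10:10 stratified/group-aware dataset split,
  k-means anchor clustering under the 1 − IoU distance, staged error-gap
  reports.
* **Pipeline + CLI** — `run_pipeline()` wires
  simulate → track → count → eval from a YAML config;
  `inst/cli/peartrack` is a thin Rscript front end
  (`simulate | track | count | eval-det | eval-count | report |
  lr-schedule`).

## Worked example

Simulate a 50-fruit orchard pass, corrupt the ideal detections with 10%
flicker plus the default occlusion/false-positive model, track, count both
ways, and evaluate:

```r
library(peartrack)

sim    <- generate_scene(scene_config(n_fruits = 50, seed = 1))
dets   <- corrupt_detections(sim, corruption_config(p_miss = 0.1, seed = 2))
sim$scene
#> <gt_scene> 50 object(s), 297 frame(s), frame 1080 x 1920 px
dets
#> <detections> 3773 detections over 280 frame(s)

tracks <- run_tracker(dets, tracker_config(), n_frames = sim$scene$n_frames)
tracks
#> <track_set> 137 track(s), 55 ever confirmed

H <- sim$scene$frame_size[2]
count_unique_ids(tracks)
#> <count_record> method unique_id: total 55
count_roi_line(tracks, H)
#> <count_record> method roi_line: total 45

m <- match_counts_to_gt(count_unique_ids(tracks), tracks, sim$scene)
counting_metrics(m$TP, m$FP, m$FN, total_gt = n_objects(sim$scene))
#> <count_eval_report>
#>   TP 50  FP 5  FN 0  mismatches 0  total_gt 50
#>   R 100.00%  FN rate 0.00%  P 90.91%  FP rate 10.00%
#>   F1 95.24%  MOTA 90.00%

evaluate_detections(dets, sim$scene, eval_config())
#> <det_eval_report>
#>   TP 3709  FP 54  FN 1342
#>   P 0.9856  R 0.7343  F1 0.8416  FNR 0.2657  FPR 0.0144
#>   avg IoU 0.9250  AP(11pt) 0.7246
```

Reading the numbers: the detector-level recall is 0.73 (flicker plus
occlusion episodes removed a quarter of the fruit-frames) at near-perfect
precision. The unique-ID counter still recovers every fruit (recall 100%)
because a fruit only needs to be tracked *somewhere* in its pass, but
occlusion-born track fragmentation books 5 duplicate identities (precision
90.91%, MOTA 90%). The ROI-line counter misses the 5 fruit whose track was
broken exactly while crossing the mid-frame line — the two counters fail
in opposite directions, which is why both are worth computing.

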