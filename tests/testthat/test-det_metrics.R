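test_that("iou matches the rasterized-grid oracle", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 5, 5)), 0)

  # oracle: count covered integer grid cells on a rasterized canvas
  raster_iou <- function(a, b, res = 60) {
    px <- expand.grid(x = seq_len(res) - 0.5, y = seq_len(res) - 0.5)
    inside <- function(b) px$x >= b[1] & px$x < b[1] + b[3] &
      px$y >= b[2] & px$y < b[2] + b[4]
    ia <- inside(a); ib <- inside(b)
    sum(ia & ib) / sum(ia | ib)
  }
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 10, 10)), 1 / 3)
  expect_equal(raster_iou(c(0, 0, 10, 10), c(5, 0, 10, 10)), 1 / 3)
  for (k in 1:20) {
    set.seed(k)
    a <- c(sample(0:20, 2), sample(5:20, 2))
    b <- c(sample(0:20, 2), sample(5:20, 2))
    expect_equal(iou(a, b), raster_iou(a, b), tolerance = 1e-12)
  }
  expect_error(iou(c(0, 0, -1, 5), c(0, 0, 1, 1)), "positive")
})

test_that("evaluate_detections applies the IoU and confidence rules", {
  gt <- gt_scene(data.frame(id = 1L, frame = 0L, x = 0, y = 0, w = 10,
                            h = 10), frame_size = c(100, 100))
  # IoU 0.6 via x-shift 2.5: overlap 75, union 125
  d <- make_dets(0L, 2.5, 0, 10, 10, 0.9)
  r <- evaluate_detections(d, gt)
  expect_equal(c(r$TP, r$FP, r$FN), c(1L, 0L, 0L))
  expect_equal(c(r$P, r$R, r$F1), c(1, 1, 1))
  expect_equal(r$avg_iou, 0.6)

  # IoU below threshold: detection is FP and the object FN
  d <- make_dets(0L, 6, 0, 10, 10, 0.9)  # overlap 40, union 160 -> 0.25
  r <- evaluate_detections(d, gt)
  expect_equal(c(r$TP, r$FP, r$FN), c(0L, 1L, 1L))

  # suppressed low-confidence detection is neither TP nor FP; object is FN
  d <- make_dets(0L, 0, 0, 10, 10, 0.1)
  r <- evaluate_detections(d, gt)
  expect_equal(c(r$TP, r$FP, r$FN), c(0L, 0L, 1L))
})

test_that("two GTs, three detections: greedy matching maximizes TP", {
  gt <- gt_scene(data.frame(id = 1:2, frame = 0L, x = c(0, 50),
                            y = c(0, 50), w = 10, h = 10),
                 frame_size = c(100, 100))
  d <- make_dets(rep(0L, 3), x = c(1, 80, 51), y = c(0, 10, 50),
                 w = rep(10, 3), h = rep(10, 3), conf = c(0.9, 0.8, 0.7))
  r <- evaluate_detections(d, gt)
  expect_equal(c(r$TP, r$FP, r$FN), c(2L, 1L, 0L))
  expect_equal(r$P, 2 / 3)
  expect_equal(r$R, 1)
})

test_that("empty ground truth makes every detection a false positive", {
  gt <- gt_scene(frame_size = c(100, 100), n_frames = 5L)
  d <- make_dets(c(0L, 1L), c(1, 2), c(1, 2), c(5, 5), c(5, 5))
  r <- suppressWarnings(evaluate_detections(d, gt))
  expect_equal(c(r$TP, r$FP, r$FN), c(0L, 2L, 0L))
})

test_that("TP count equals brute-force maximum matching on random frames", {
  set.seed(7)
  for (rep in 1:50) {
    ng <- sample(0:5, 1); nd <- sample(0:5, 1)
    gt_boxes <- if (ng) cbind(runif(ng, 0, 40), runif(ng, 0, 40),
                              runif(ng, 5, 20), runif(ng, 5, 20))
                else matrix(numeric(0), 0, 4)
    det_boxes <- if (nd) cbind(runif(nd, 0, 40), runif(nd, 0, 40),
                               runif(nd, 5, 20), runif(nd, 5, 20))
                 else matrix(numeric(0), 0, 4)
    gt <- if (ng) gt_scene(data.frame(id = seq_len(ng), frame = 0L,
                                      x = gt_boxes[, 1], y = gt_boxes[, 2],
                                      w = gt_boxes[, 3], h = gt_boxes[, 4]),
                           frame_size = c(60, 60), n_frames = 1L)
          else gt_scene(frame_size = c(60, 60), n_frames = 1L)
    d <- if (nd) make_dets(rep(0L, nd), det_boxes[, 1], det_boxes[, 2],
                           det_boxes[, 3], det_boxes[, 4],
                           conf = runif(nd, 0.5, 1))
         else detections()
    r <- suppressWarnings(evaluate_detections(d, gt))
    oracle <- brute_force_max_matching(det_boxes, gt_boxes, 0.5)
    expect_equal(r$TP, oracle)
  }
})

test_that("report identities hold: FNR + R = 1, FPR + P = 1, F1 bounds", {
  set.seed(11)
  for (rep in 1:10) {
    ng <- sample(1:6, 1); nd <- sample(1:6, 1)
    gt <- gt_scene(data.frame(id = seq_len(ng), frame = 0L,
                              x = runif(ng, 0, 40), y = runif(ng, 0, 40),
                              w = runif(ng, 5, 20), h = runif(ng, 5, 20)),
                   frame_size = c(60, 60), n_frames = 1L)
    d <- make_dets(rep(0L, nd), runif(nd, 0, 40), runif(nd, 0, 40),
                   runif(nd, 5, 20), runif(nd, 5, 20),
                   conf = runif(nd, 0.3, 1))
    r <- suppressWarnings(evaluate_detections(d, gt))
    expect_equal(r$FNR + r$R, 1)
    expect_equal(r$FPR + r$P, 1)
    expect_gte(r$F1, 0)
    expect_lte(r$F1, min(1, (r$P + r$R) / 2 + 1e-12))
  }
})

test_that("raising the confidence threshold never increases TP", {
  set.seed(3)
  ng <- 6; nd <- 10
  gt <- gt_scene(data.frame(id = seq_len(ng), frame = 0L,
                            x = runif(ng, 0, 80), y = runif(ng, 0, 80),
                            w = runif(ng, 10, 20), h = runif(ng, 10, 20)),
                 frame_size = c(100, 100), n_frames = 1L)
  d <- make_dets(rep(0L, nd), runif(nd, 0, 80), runif(nd, 0, 80),
                 runif(nd, 10, 20), runif(nd, 10, 20), conf = runif(nd))
  tps <- vapply(seq(0, 1, by = 0.1), function(ct)
    suppressWarnings(
      evaluate_detections(d, gt, eval_config(confidence_threshold = ct)))$TP,
    integer(1L))
  expect_true(all(diff(tps) <= 0L))
})

test_that("11-point AP reproduces the hand-enumerated curve", {
  # perfect detector
  expect_equal(average_precision_11pt(rep(TRUE, 4), 4), 1)
  # no detections
  expect_equal(average_precision_11pt(logical(0), 3), 0)
  # TP, FP, TP with 2 ground truths:
  # recalls .5, .5, 1; precisions 1, .5, 2/3
  # interpolated: 1 for r <= .5 (6 points), 2/3 for r > .5 (5 points)
  expect_equal(average_precision_11pt(c(TRUE, FALSE, TRUE), 2), 28 / 33)
  # zero ground truth with detections warns and returns 0
  expect_warning(ap <- average_precision_11pt(c(TRUE), 0), "ground-truth")
  expect_equal(ap, 0)
})

test_that("AP is invariant to the input order of tied confidences", {
  gt <- gt_scene(data.frame(id = 1:2, frame = 0L, x = c(0, 50), y = c(0, 0),
                            w = 10, h = 10), frame_size = c(100, 100))
  d1 <- make_dets(rep(0L, 2), c(0, 50), c(0, 0), c(10, 10), c(10, 10),
                  conf = c(0.8, 0.8))
  d2 <- d1[2:1, ]
  r1 <- evaluate_detections(as_detections(as.data.frame(d1)), gt)
  r2 <- evaluate_detections(as_detections(as.data.frame(d2)), gt)
  expect_equal(r1$AP, r2$AP)
})

test_that("the report CSV mirrors the flat layout in percent", {
  gt <- make_linear_gt()
  d <- make_linear_dets()
  r <- evaluate_detections(d, gt)
  f <- withr::local_tempfile(fileext = ".csv")
  write_det_report(list(run1 = r), f)
  got <- read.csv(f)
  expect_equal(names(got), c("run", "TP", "FP", "FN", "P", "FPR", "R",
                             "FNR", "F1", "avg_iou", "AP"))
  expect_equal(got$P, 100)
})
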