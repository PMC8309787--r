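# Shared fixture builders. Everything is generated in code; no binary data.

# A tiny deterministic detection stream: one box per (frame, spec row).
make_dets <- function(frame, x, y, w, h, conf = rep(0.9, length(frame)),
                      embedding = NULL) {
  detections(frame = frame, x = x, y = y, w = w, h = h, conf = conf,
             embedding = embedding)
}

# Ground truth with a single object following y = y0 + vy * frame.
make_linear_gt <- function(id = 1L, frames = 0:9, x = 10, y0 = 0, vy = 5,
                           w = 10, h = 10, frame_size = c(100, 100)) {
  gt_scene(data.frame(id = id, frame = frames, x = x, y = y0 + vy * frames,
                      w = w, h = h),
           frame_size = frame_size, n_frames = max(frames) + 1L)
}

# Ideal detections for a linear-motion object (confidence 1).
make_linear_dets <- function(frames = 0:9, x = 10, y0 = 0, vy = 5,
                             w = 10, h = 10, conf = 1) {
  make_dets(frames, rep(x, length(frames)), y0 + vy * frames,
            rep(w, length(frames)), rep(h, length(frames)),
            rep(conf, length(frames)))
}

# Random unit vector helper for appearance fixtures.
runit <- function(d) { v <- rnorm(d); v / sqrt(sum(v^2)) }

# Hand-built finished track with a given centroid path and detection flags,
# bypassing the tracker.
make_track <- function(id, frames, cy, cx = 50, w = 10, h = 10,
                       had = rep(TRUE, length(frames)),
                       confirmed = TRUE) {
  history <- lapply(seq_along(frames), function(i)
    list(frame = as.integer(frames[i]),
         box = c(x = cx - w / 2, y = cy[i] - h / 2, w = w, h = h),
         had_detection = had[i]))
  structure(list(id = as.integer(id), mean = rep(0, 8), cov = diag(8),
                 status = "deleted", ever_confirmed = confirmed,
                 hits = sum(had), time_since_update = 0L,
                 first_frame = as.integer(frames[1L]),
                 last_frame = as.integer(frames[length(frames)]),
                 history = history, gallery = list()),
            class = "track")
}

as_track_set <- function(...) structure(list(...), class = "track_set")

# Brute-force minimum-cost maximum-feasibility assignment for small
# matrices; the independent oracle for hungarian_assign. Enumerates all
# injections of the smaller side into the larger.
brute_force_assignment <- function(cost, infeasible_cost = Inf) {
  m <- nrow(cost); n <- ncol(cost)
  feasible <- is.finite(cost) & cost < infeasible_cost
  best <- list(size = -1L, cost = Inf)
  rows <- seq_len(m)
  explore <- function(i, used_cols, size, total) {
    if (i > m) {
      if (size > best$size ||
          (size == best$size && total < best$cost - 1e-12)) {
        best <<- list(size = size, cost = total)
      }
      return(invisible())
    }
    explore(i + 1L, used_cols, size, total)          # row i unmatched
    for (j in seq_len(n)) {
      if (!used_cols[j] && feasible[i, j])
        explore(i + 1L, replace(used_cols, j, TRUE), size + 1L,
                total + cost[i, j])
    }
  }
  if (m == 0L || n == 0L) return(list(size = 0L, cost = 0))
  explore(1L, rep(FALSE, n), 0L, 0)
  best
}

# Brute-force maximum-cardinality IoU-feasible matching of detections to
# ground-truth boxes on one frame: the oracle for evaluate_detections TP.
brute_force_max_matching <- function(det_boxes, gt_boxes, thr) {
  nd <- nrow(det_boxes); ng <- nrow(gt_boxes)
  if (nd == 0L || ng == 0L) return(0L)
  M <- matrix(0, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng))
    M[i, j] <- iou(det_boxes[i, ], gt_boxes[j, ])
  feasible <- M >= thr
  best <- 0L
  explore <- function(i, used, size) {
    if (size + (nd - i + 1L) <= best) return(invisible())
    if (i > nd) { best <<- max(best, size); return(invisible()) }
    explore(i + 1L, used, size)
    for (j in seq_len(ng))
      if (!used[j] && feasible[i, j])
        explore(i + 1L, replace(used, j, TRUE), size + 1L)
  }
  explore(1L, rep(FALSE, ng), 0L)
  best
}
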