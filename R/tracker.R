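# Online multi-object tracker: constant-velocity Kalman prediction,
# Mahalanobis-gated motion+appearance association solved by the Hungarian
# algorithm with a matching cascade, and a tentative/confirmed/deleted
# lifecycle.

#' Tracker configuration
#'
#' @param n_init consecutive hits before a tentative track is confirmed
#'   (default 3).
#' @param max_age frames a confirmed track may coast without a detection
#'   before deletion (default 30).
#' @param gate_quantile chi-square quantile for Mahalanobis gating on the
#'   (cx, cy, aspect, height) measurement, 4 degrees of freedom
#'   (default 0.95).
#' @param cost_mode association cost: `"iou"` (1 - IoU of predicted and
#'   detected boxes), `"appearance"` (minimum cosine distance to the track's
#'   embedding gallery) or `"combined"`
#'   (`lambda * appearance + (1 - lambda) * (1 - IoU)`); `combined` falls
#'   back to pure IoU when the stream carries no embeddings.
#' @param appearance_weight lambda in \[0, 1\] for `combined` (default 0.5).
#' @param gallery_size appearance vectors retained per track, FIFO
#'   (default 100).
#' @param max_iou_cost IoU costs above this are forbidden pairs
#'   (default 0.7).
#' @param max_appearance_cost cascade matches whose cosine distance to the
#'   track gallery exceeds this budget are forbidden (default 0.25); only
#'   active when embeddings are available.
#' @return A `tracker_config` list.
#' @export
tracker_config <- function(n_init = 3L, max_age = 30L, gate_quantile = 0.95,
                           cost_mode = c("combined", "iou", "appearance"),
                           appearance_weight = 0.5, gallery_size = 100L,
                           max_iou_cost = 0.7, max_appearance_cost = 0.25) {
  cost_mode <- match.arg(cost_mode)
  stopifnot(n_init >= 1L, max_age >= 1L,
            gate_quantile > 0, gate_quantile < 1,
            appearance_weight >= 0, appearance_weight <= 1,
            gallery_size >= 1L, max_iou_cost > 0, max_appearance_cost > 0)
  structure(list(n_init = as.integer(n_init), max_age = as.integer(max_age),
                 gate_quantile = gate_quantile, cost_mode = cost_mode,
                 appearance_weight = appearance_weight,
                 gallery_size = as.integer(gallery_size),
                 max_iou_cost = max_iou_cost,
                 max_appearance_cost = max_appearance_cost,
                 gate_threshold = stats::qchisq(gate_quantile, df = 4)),
            class = "tracker_config")
}

#' Start a track from a detection
#'
#' Initializes the Kalman state at the detection's centroid/aspect/height
#' with zero velocities and a covariance scaled by the detection height;
#' the track starts tentative with one hit.
#'
#' @param det one-row [detections] data.frame (or list with x, y, w, h and
#'   optionally embedding).
#' @param frame 0-based frame of birth.
#' @param next_id track identifier to assign.
#' @return A `track` object.
#' @export
init_track <- function(det, frame, next_id) {
  z <- box_to_measurement(det$x, det$y, det$w, det$h)
  kf <- kf_initiate(z)
  gallery <- list()
  emb <- det$embedding
  if (!is.null(emb)) {
    if (is.list(emb)) emb <- emb[[1L]]
    if (!is.null(emb)) gallery <- list(as.numeric(emb))
  }
  structure(list(id = as.integer(next_id), mean = kf$mean, cov = kf$cov,
                 status = "tentative", ever_confirmed = FALSE,
                 hits = 1L, time_since_update = 0L,
                 first_frame = as.integer(frame),
                 last_frame = as.integer(frame),
                 history = list(list(frame = as.integer(frame),
                                     box = measurement_to_box(z),
                                     had_detection = TRUE)),
                 gallery = gallery),
            class = "track")
}

#' Advance a track one frame
#'
#' Applies the constant-velocity transition and inflates the covariance with
#' process noise; increments `time_since_update`.
#'
#' @param track a `track`.
#' @return The predicted track.
#' @export
predict_track <- function(track) {
  if (track$status == "deleted")
    stop("cannot predict a deleted track", call. = FALSE)
  kf <- kf_predict(track$mean, track$cov)
  track$mean <- kf$mean
  track$cov <- kf$cov
  track$time_since_update <- track$time_since_update + 1L
  track
}

track_box <- function(track) measurement_to_box(track$mean[1:4])

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear sum assignment problem. Pairs whose cost is
#' at or above `infeasible_cost` are forbidden; among assignments that match
#' as many feasible pairs as possible, the total cost is minimized.
#'
#' @param cost numeric m x n matrix.
#' @param infeasible_cost sentinel at/above which a pair is forbidden
#'   (default `Inf`).
#' @return List with `matches` (2-column matrix of row, col indices),
#'   `unmatched_rows`, `unmatched_cols`.
#' @export
hungarian_assign <- function(cost, infeasible_cost = Inf) {
  cost <- as.matrix(cost)
  m <- nrow(cost); n <- ncol(cost)
  if (m == 0L || n == 0L)
    return(list(matches = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("row", "col"))),
                unmatched_rows = seq_len(m), unmatched_cols = seq_len(n)))
  forbidden <- !is.finite(cost) | cost >= infeasible_cost
  work <- cost
  feas <- work[!forbidden]
  # big-M padding: forbidding dominates, so feasibility is maximized first
  big <- if (length(feas)) (max(abs(feas)) + 1) * (min(m, n) + 1) * 1e3 else 1
  work[forbidden] <- big
  assign <- .lsap_solve(work)
  rows <- which(!is.na(assign))
  cols <- assign[rows]
  ok <- !forbidden[cbind(rows, cols)]
  matches <- cbind(row = rows[ok], col = cols[ok])
  matches <- matches[order(matches[, 1L]), , drop = FALSE]
  list(matches = matches,
       unmatched_rows = setdiff(seq_len(m), matches[, 1L]),
       unmatched_cols = setdiff(seq_len(n), matches[, 2L]))
}

# Cosine distance of each detection embedding to the nearest gallery vector.
appearance_cost <- function(tracks, dets) {
  nd <- nrow(dets)
  out <- matrix(1, length(tracks), nd)
  if (is.null(dets$embedding))
    stop("appearance association needs detection embeddings", call. = FALSE)
  E <- do.call(rbind, lapply(dets$embedding, function(e) {
    if (is.null(e)) stop("appearance association needs detection embeddings",
                         call. = FALSE)
    as.numeric(e)
  }))
  for (i in seq_along(tracks)) {
    g <- tracks[[i]]$gallery
    if (!length(g)) next
    G <- do.call(rbind, g)
    sims <- E %*% t(G)            # unit vectors: dot product = cosine
    out[i, ] <- 1 - apply(sims, 1L, max)
  }
  out
}

# Build the association cost for a set of tracks vs detections, with
# forbidden pairs marked Inf (Mahalanobis gate; IoU ceiling in iou mode).
association_cost <- function(tracks, dets, cfg, use_iou_only = FALSE) {
  nt <- length(tracks); nd <- nrow(dets)
  if (nt == 0L || nd == 0L) return(matrix(numeric(0), nt, nd))
  det_boxes <- as.matrix(dets[c("x", "y", "w", "h")])
  trk_boxes <- do.call(rbind, lapply(tracks, track_box))
  iou_cost <- 1 - iou_matrix(trk_boxes, det_boxes)

  have_emb <- !is.null(dets$embedding) &&
    !any(vapply(dets$embedding, is.null, logical(1L)))
  mode <- if (use_iou_only) "iou" else cfg$cost_mode
  if (mode == "combined" && !have_emb) mode <- "iou"
  if (mode == "appearance" && !have_emb)
    stop("appearance association needs detection embeddings", call. = FALSE)

  app_cost <- if (mode %in% c("appearance", "combined"))
    appearance_cost(tracks, dets) else NULL
  cost <- switch(mode,
    iou = iou_cost,
    appearance = app_cost,
    combined = cfg$appearance_weight * app_cost +
      (1 - cfg$appearance_weight) * iou_cost)

  if (use_iou_only) {
    # IoU stage: forbidden when the boxes barely overlap. The Mahalanobis
    # gate is deliberately not applied here — newborn tracks on frame-edge
    # clipped boxes violate it while the box is still growing into view.
    cost[iou_cost > cfg$max_iou_cost] <- Inf
  } else if (!is.null(app_cost)) {
    # With a discriminative appearance metric the cascade is gated by the
    # appearance budget: a pair is admissible only when the detection looks
    # like the track. Motion still shapes the combined cost, but a strict
    # Mahalanobis gate would orphan tracks whose constant-velocity model is
    # transiently wrong (boxes clipped while entering the frame, flicker
    # gaps spanning the entry transition), which is exactly when the
    # appearance signal should take over.
    for (i in seq_len(nt))
      cost[i, app_cost[i, ] > cfg$max_appearance_cost] <- Inf
  } else {
    Z <- t(apply(det_boxes, 1L, function(b)
      box_to_measurement(b[1L], b[2L], b[3L], b[4L])))
    for (i in seq_len(nt)) {
      d2 <- kf_gating_distance(tracks[[i]]$mean, tracks[[i]]$cov, Z)
      gate <- d2 > cfg$gate_threshold
      if (mode == "iou") gate <- gate | iou_cost[i, ] > cfg$max_iou_cost
      cost[i, gate] <- Inf
    }
  }
  cost
}

#' Associate predicted tracks with detections
#'
#' Confirmed tracks are matched first in ascending `time_since_update`
#' (matching cascade) with the configured cost; remaining tracks and
#' detections then go through an IoU association. Pairs beyond the
#' chi-square Mahalanobis gate (or above `max_iou_cost` in IoU mode) are
#' forbidden.
#'
#' @param tracks list of predicted `track`s.
#' @param dets [detections] of the current frame.
#' @param cfg a [tracker_config].
#' @return List with `matches` (2-column matrix: track index, detection
#'   index), `unmatched_tracks`, `unmatched_detections`.
#' @export
associate <- function(tracks, dets, cfg = tracker_config()) {
  nt <- length(tracks); nd <- if (is.null(dets)) 0L else nrow(dets)
  matches <- matrix(integer(0), 0, 2)
  if (nt == 0L || nd == 0L)
    return(list(matches = matches, unmatched_tracks = seq_len(nt),
                unmatched_detections = seq_len(nd)))

  confirmed <- which(vapply(tracks, function(t) t$status == "confirmed",
                            logical(1L)))
  free_dets <- seq_len(nd)

  # cascade over track age
  if (length(confirmed)) {
    ages <- vapply(tracks[confirmed], `[[`, integer(1L), "time_since_update")
    for (age in sort(unique(ages))) {
      level <- confirmed[ages == age]
      if (!length(free_dets)) break
      cost <- association_cost(tracks[level],
                               dets[free_dets, , drop = FALSE], cfg)
      res <- hungarian_assign(cost)
      if (nrow(res$matches))
        matches <- rbind(matches, cbind(level[res$matches[, 1L]],
                                        free_dets[res$matches[, 2L]]))
      if (nrow(res$matches))
        free_dets <- free_dets[-res$matches[, 2L]]
    }
  }

  # IoU association for everything still unmatched
  remaining <- setdiff(seq_len(nt), matches[, 1L])
  if (length(remaining) && length(free_dets)) {
    cost <- association_cost(tracks[remaining],
                             dets[free_dets, , drop = FALSE], cfg,
                             use_iou_only = TRUE)
    res <- hungarian_assign(cost)
    if (nrow(res$matches))
      matches <- rbind(matches, cbind(remaining[res$matches[, 1L]],
                                      free_dets[res$matches[, 2L]]))
  }

  matches <- matches[order(matches[, 1L]), , drop = FALSE]
  colnames(matches) <- c("track", "det")
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), matches[, 1L]),
       unmatched_detections = setdiff(seq_len(nd), matches[, 2L]))
}

new_tracker_state <- function(cfg) {
  list(active = list(), finished = list(), next_id = 1L, last_frame = -1L,
       cfg = cfg)
}

finalize_track <- function(track) {
  # truncate trailing predicted-only frames: the lifespan ends at the last
  # frame with a detection
  had <- vapply(track$history, `[[`, logical(1L), "had_detection")
  last_det <- max(which(had))
  track$history <- track$history[seq_len(last_det)]
  track$last_frame <- track$history[[last_det]]$frame
  track$status <- "deleted"
  track
}

#' Advance the tracker by one frame of detections
#'
#' Predicts all live tracks, associates them with the frame's detections,
#' Kalman-updates the matched ones (appending embeddings to a bounded FIFO
#' gallery and confirming tentative tracks after `n_init` hits), marks the
#' unmatched ones missed (tentative tracks die on their first miss; confirmed
#' tracks die after `max_age` missed frames) and spawns tentative tracks from
#' unmatched detections.
#'
#' @param state tracker state from `new_tracker_state()` or a previous
#'   `step_tracker()` call.
#' @param dets detections of this frame (may be empty).
#' @param frame 0-based frame index; must be strictly increasing across
#'   calls.
#' @return The updated state.
#' @export
step_tracker <- function(state, dets, frame) {
  cfg <- state$cfg
  frame <- as.integer(frame)
  if (frame <= state$last_frame)
    stop("frames must be presented in strictly increasing order",
         call. = FALSE)
  state$last_frame <- frame

  state$active <- lapply(state$active, predict_track)
  res <- associate(state$active, dets, cfg)

  keep <- rep(TRUE, length(state$active))
  if (nrow(res$matches)) for (k in seq_len(nrow(res$matches))) {
    ti <- res$matches[k, 1L]; di <- res$matches[k, 2L]
    tr <- state$active[[ti]]
    z <- box_to_measurement(dets$x[di], dets$y[di], dets$w[di], dets$h[di])
    kf <- kf_update(tr$mean, tr$cov, z)
    tr$mean <- kf$mean; tr$cov <- kf$cov
    tr$hits <- tr$hits + 1L
    tr$time_since_update <- 0L
    if (!is.null(dets$embedding)) {
      e <- dets$embedding[[di]]
      if (!is.null(e)) {
        tr$gallery <- c(tr$gallery, list(as.numeric(e)))
        if (length(tr$gallery) > cfg$gallery_size)
          tr$gallery <- tail(tr$gallery, cfg$gallery_size)
      }
    }
    if (tr$status == "tentative" && tr$hits >= cfg$n_init) {
      tr$status <- "confirmed"
      tr$ever_confirmed <- TRUE
    }
    tr$history <- c(tr$history, list(list(frame = frame,
                                          box = track_box(tr),
                                          had_detection = TRUE)))
    tr$last_frame <- frame
    state$active[[ti]] <- tr
  }

  for (ti in res$unmatched_tracks) {
    tr <- state$active[[ti]]
    if (tr$status == "tentative" || tr$time_since_update > cfg$max_age) {
      state$finished <- c(state$finished, list(finalize_track(tr)))
      keep[ti] <- FALSE
    } else {
      tr$history <- c(tr$history, list(list(frame = frame,
                                            box = track_box(tr),
                                            had_detection = FALSE)))
      tr$last_frame <- frame
      state$active[[ti]] <- tr
    }
  }
  state$active <- state$active[keep]

  for (di in res$unmatched_detections) {
    tr <- init_track(dets[di, , drop = FALSE], frame, state$next_id)
    if (cfg$n_init <= 1L) {
      tr$status <- "confirmed"; tr$ever_confirmed <- TRUE
    }
    state$next_id <- state$next_id + 1L
    state$active <- c(state$active, list(tr))
  }
  state
}

#' Run the tracker over a detection stream
#'
#' Iterates [step_tracker()] over every frame from 0 to the last frame of the
#' stream (or `n_frames - 1`), then finalizes all live tracks. The tracker is
#' online: the state at frame t depends only on frames at or before t, and
#' the output is deterministic given the stream and configuration.
#'
#' @param dets a [detections] stream grouped by frame.
#' @param cfg a [tracker_config].
#' @param n_frames optional total frame count (to keep coasting/deletion
#'   bookkeeping running past the last detection).
#' @return A list of finished `track` objects (class `track_set`).
#' @export
run_tracker <- function(dets, cfg = tracker_config(), n_frames = NULL) {
  dets <- as_detections(as.data.frame(dets))
  if (!nrow(dets) && is.null(n_frames))
    return(structure(list(), class = "track_set"))
  last <- if (is.null(n_frames)) max(dets$frame) else n_frames - 1L
  by_frame <- split(seq_len(nrow(dets)), dets$frame)
  state <- new_tracker_state(cfg)
  for (f in 0:last) {
    idx <- by_frame[[as.character(f)]]
    frame_dets <- if (is.null(idx)) dets[0, , drop = FALSE]
                  else dets[idx, , drop = FALSE]
    state <- step_tracker(state, frame_dets, f)
  }
  finished <- c(state$finished, lapply(state$active, finalize_track))
  ids <- vapply(finished, `[[`, integer(1L), "id")
  structure(finished[order(ids)], class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  conf <- sum(vapply(x, `[[`, logical(1L), "ever_confirmed"))
  cat(sprintf("<track_set> %d track(s), %d ever confirmed\n", length(x), conf))
  invisible(x)
}

# Flat data.frame view of a track's history.
track_history_df <- function(track) {
  data.frame(frame = vapply(track$history, `[[`, integer(1L), "frame"),
             x = vapply(track$history, function(h) h$box[["x"]], numeric(1L)),
             y = vapply(track$history, function(h) h$box[["y"]], numeric(1L)),
             w = vapply(track$history, function(h) h$box[["w"]], numeric(1L)),
             h = vapply(track$history, function(h) h$box[["h"]], numeric(1L)),
             had_detection = vapply(track$history, `[[`, logical(1L),
                                    "had_detection"))
}

#' Write tracks in the MOT-challenge result dialect
#'
#' Lines `frame,id,bb_left,bb_top,bb_width,bb_height,conf,-1,-1,-1` with
#' 1-based frames; only tracks that were ever confirmed are written, one line
#' per history frame (conf 1 for detected frames, 0 for predicted-only).
#'
#' @param tracks a `track_set` from [run_tracker()].
#' @param path output file.
#' @export
write_tracks <- function(tracks, path) {
  lines <- character(0)
  for (tr in tracks) {
    if (!tr$ever_confirmed) next
    h <- track_history_df(tr)
    lines <- c(lines, sprintf("%d,%d,%s,%s,%s,%s,%d,-1,-1,-1",
                              h$frame + 1L, tr$id, fmt_num(h$x), fmt_num(h$y),
                              fmt_num(h$w), fmt_num(h$h),
                              as.integer(h$had_detection)))
  }
  writeLines(lines, path)
  invisible(path)
}
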