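test_that("init_track sets the state from the detection box", {
  d <- make_dets(0L, 10, 10, 4, 8)
  tr <- init_track(d, 0L, 1L)
  expect_equal(tr$mean, c(12, 14, 0.5, 8, 0, 0, 0, 0))
  expect_equal(tr$status, "tentative")
  expect_equal(tr$hits, 1L)
  expect_equal(length(tr$gallery), 0L)
  # with embedding, gallery length 1
  d2 <- make_dets(0L, 0, 0, 4, 8, embedding = list(runit(8)))
  expect_equal(length(init_track(d2, 0L, 2L)$gallery), 1L)
})

test_that("prediction follows constant velocity and inflates covariance", {
  d <- make_dets(0L, 10, 10, 4, 8)
  tr <- init_track(d, 0L, 1L)
  p <- predict_track(tr)
  expect_equal(p$mean[1], 12)          # zero velocity: position unchanged
  tr$mean[5] <- 2                      # vx = 2
  p <- predict_track(tr)
  expect_equal(p$mean[1], 14)
  expect_equal(p$time_since_update, 1L)
})

test_that("the Kalman recursion matches an independent textbook filter", {
  # independent oracle: direct matrix recursion with the same noise model
  d <- make_dets(0L, 10, 20, 10, 20)
  tr <- init_track(d, 0L, 1L)
  mean <- tr$mean; cov <- tr$cov
  F <- diag(8); F[cbind(1:4, 5:8)] <- 1
  measurements <- list(c(16, 31, 0.5, 20), c(22, 42, 0.5, 20))
  for (z in measurements) {
    h <- mean[4]
    Q <- diag(c(h / 20, h / 20, 5e-2, h / 20,
                h / 160, h / 160, 1e-5, h / 160)^2)
    mean <- as.numeric(F %*% mean); cov <- F %*% cov %*% t(F) + Q
    H <- cbind(diag(4), matrix(0, 4, 4))
    R <- diag(c(mean[4] / 20, mean[4] / 20, 1e-1, mean[4] / 20)^2)
    S <- H %*% cov %*% t(H) + R
    K <- cov %*% t(H) %*% solve(S)
    mean <- as.numeric(mean + K %*% (z - H %*% mean))
    cov <- cov - K %*% S %*% t(K)

    tr <- predict_track(tr)
    kf <- peartrack:::kf_update(tr$mean, tr$cov, z)
    tr$mean <- kf$mean; tr$cov <- kf$cov
    tr$time_since_update <- 0L
    expect_equal(tr$mean, mean, tolerance = 1e-8)
    expect_equal(tr$cov, cov, tolerance = 1e-6)
  }
})

test_that("predicted diagonal covariance strictly grows under process noise", {
  d <- make_dets(0L, 10, 10, 10, 20)
  tr <- init_track(d, 0L, 1L)
  before <- diag(tr$cov)[1:4]
  after <- diag(predict_track(tr)$cov)[1:4]
  expect_true(all(after > before))
})

test_that("hungarian_assign solves small canonical cases", {
  r <- hungarian_assign(matrix(0.1, 1, 1))
  expect_equal(unname(r$matches), matrix(c(1L, 1L), 1))
  r <- hungarian_assign(matrix(c(0.1, 0.9, 0.9, 0.1), 2, byrow = TRUE))
  expect_equal(unname(r$matches[, 2]), c(1L, 2L))
  # empty matrix
  r <- hungarian_assign(matrix(numeric(0), 0, 3))
  expect_equal(r$unmatched_cols, 1:3)
  # forbidden pairs are never returned
  cost <- matrix(c(0.1, Inf, Inf, 0.2), 2, byrow = TRUE)
  r <- hungarian_assign(cost)
  expect_equal(unname(r$matches), cbind(1:2, 1:2))
  # fully forbidden row stays unmatched
  cost <- matrix(c(Inf, Inf, 0.3, 0.1), 2, byrow = TRUE)
  r <- hungarian_assign(cost)
  expect_equal(r$unmatched_rows, 1L)
})

test_that("hungarian_assign equals brute-force enumeration on random matrices", {
  set.seed(99)
  for (rep in 1:120) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    cost <- matrix(runif(m * n), m, n)
    if (runif(1) < 0.4) cost[runif(m * n) < 0.3] <- Inf
    r <- hungarian_assign(cost)
    got_cost <- if (nrow(r$matches)) sum(cost[r$matches]) else 0
    oracle <- brute_force_assignment(cost)
    expect_equal(nrow(r$matches), oracle$size)
    expect_equal(got_cost, oracle$cost, tolerance = 1e-9)
  }
})

test_that("association matches exact overlaps and respects gating", {
  cfg <- tracker_config(cost_mode = "iou")
  d0 <- make_dets(0L, 10, 10, 10, 10, 1)
  tr <- init_track(d0, 0L, 1L)
  tr$status <- "confirmed"
  p <- predict_track(tr)
  res <- associate(list(p), make_dets(1L, 10, 10, 10, 10, 1), cfg)
  expect_equal(nrow(res$matches), 1L)
  # a detection far beyond the gate leaves both unmatched
  res <- associate(list(p), make_dets(1L, 500, 500, 10, 10, 1), cfg)
  expect_equal(res$unmatched_tracks, 1L)
  expect_equal(res$unmatched_detections, 1L)
})

test_that("crossed two-track assignment equals the enumeration minimum", {
  cfg <- tracker_config(cost_mode = "iou")
  t1 <- init_track(make_dets(0L, 0, 0, 10, 10, 1), 0L, 1L)
  t2 <- init_track(make_dets(0L, 6, 0, 10, 10, 1), 0L, 2L)
  t1$status <- t2$status <- "confirmed"
  preds <- list(predict_track(t1), predict_track(t2))
  dets <- make_dets(c(1L, 1L), c(5, 1), c(0, 0), c(10, 10), c(10, 10),
                    c(1, 1))
  res <- associate(preds, dets, cfg)
  boxes <- lapply(preds, peartrack:::track_box)
  cost <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    cost[i, j] <- 1 - iou(boxes[[i]],
                          c(dets$x[j], dets$y[j], dets$w[j], dets$h[j]))
  oracle <- brute_force_assignment(cost)
  got <- sum(cost[res$matches[, , drop = FALSE]])
  expect_equal(got, oracle$cost, tolerance = 1e-9)
})

test_that("a clean single-object stream yields one confirmed 5-frame track", {
  d <- make_linear_dets(frames = 0:4)
  tracks <- run_tracker(d, tracker_config(cost_mode = "iou"))
  expect_equal(length(tracks), 1L)
  expect_true(tracks[[1]]$ever_confirmed)
  h <- peartrack:::track_history_df(tracks[[1]])
  expect_equal(h$frame, 0:4)
  expect_true(all(h$had_detection))
})

test_that("a long absence deletes the track and re-detection makes a new id", {
  cfg <- tracker_config(cost_mode = "iou", max_age = 5L)
  frames <- c(0:5, 20:25)
  d <- make_linear_dets(frames = frames, vy = 2)
  tracks <- run_tracker(d, cfg, n_frames = 26L)
  confirmed <- Filter(function(t) t$ever_confirmed, tracks)
  expect_equal(length(confirmed), 2L)
  expect_equal(sort(vapply(confirmed, `[[`, integer(1L), "first_frame")),
               c(0L, 20L))
  # ids never reused
  ids <- vapply(tracks, `[[`, integer(1L), "id")
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("two parallel objects keep distinct ids for 50 frames", {
  f <- 0:49
  d <- as_detections(rbind(
    as.data.frame(make_linear_dets(frames = f, x = 10, y0 = 0, vy = 2)),
    as.data.frame(make_linear_dets(frames = f, x = 60, y0 = 0, vy = 2))))
  tracks <- run_tracker(d, tracker_config(cost_mode = "iou"))
  confirmed <- Filter(function(t) t$ever_confirmed, tracks)
  expect_equal(length(confirmed), 2L)
  for (t in confirmed) {
    h <- peartrack:::track_history_df(t)
    expect_equal(length(unique(round(h$x))), 1L)  # never swapped columns
    expect_equal(nrow(h), 50L)
  }
})

test_that("exact linear motion predictions converge on the true centroid", {
  d <- make_linear_dets(frames = 0:19, vy = 4)
  st <- peartrack:::new_tracker_state(tracker_config(cost_mode = "iou"))
  errs <- numeric(0)
  for (f in 0:19) {
    st <- step_tracker(st, d[d$frame == f, ], f)
    p <- predict_track(st$active[[1L]])
    errs <- c(errs, abs(p$mean[2] - (5 + 4 * (f + 1))))
  }
  # the filter carries fixed height-scaled noise, so convergence is
  # asymptotic: the one-step prediction error shrinks from the full
  # unlearned velocity (4 px) to well under a pixel
  expect_lt(errs[20], 0.2)
  expect_lt(errs[20], errs[3] / 10)
})

test_that("the tracker is online: truncated streams reproduce prefixes", {
  set.seed(5)
  sim <- generate_scene(scene_config(n_fruits = 6, frame_size = c(300, 400),
                                     camera_speed = 20,
                                     fruit_size_range = c(40, 80),
                                     strip_length = 600, seed = 8))
  d <- corrupt_detections(sim, corruption_config(p_miss = 0.2,
                                                 occlusion_rate = 0,
                                                 fp_rate = 0.1, seed = 9))
  cut <- 25L
  full <- run_tracker(d, tracker_config(), n_frames = sim$scene$n_frames)
  pre <- run_tracker(d[d$frame < cut, , drop = FALSE], tracker_config(),
                     n_frames = cut)
  # every track the prefix run confirms exists identically (same id, same
  # boxes) in the full run, restricted to frames < cut
  hist_upto <- function(t, cut) {
    h <- peartrack:::track_history_df(t)
    h[h$frame < cut, ]
  }
  full_ids <- vapply(full, `[[`, integer(1L), "id")
  for (t in pre) {
    expect_true(t$id %in% full_ids)
    ft <- full[[which(full_ids == t$id)]]
    hp <- hist_upto(t, cut)
    hf <- hist_upto(ft, cut)
    expect_equal(hp$frame[hp$had_detection], hf$frame[hf$had_detection])
    shared <- hp$frame[hp$had_detection]
    expect_equal(hp[hp$frame %in% shared, ], hf[hf$frame %in% shared, ],
                 ignore_attr = TRUE)
  }
})

test_that("re-running the tracker gives identical output", {
  sim <- generate_scene(scene_config(n_fruits = 8, frame_size = c(300, 400),
                                     camera_speed = 20,
                                     fruit_size_range = c(40, 80),
                                     strip_length = 800, seed = 21))
  d <- corrupt_detections(sim, corruption_config(seed = 22))
  t1 <- run_tracker(d, tracker_config(), n_frames = sim$scene$n_frames)
  t2 <- run_tracker(d, tracker_config(), n_frames = sim$scene$n_frames)
  expect_identical(t1, t2)
})

test_that("track output round-trips through the MOT result dialect", {
  d <- make_linear_dets(frames = 0:6)
  tracks <- run_tracker(d, tracker_config(cost_mode = "iou"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_tracks(tracks, f)
  lines <- readLines(f)
  expect_equal(length(lines), 7L)
  expect_match(lines[1], "^1,1,")
})

test_that("out-of-order frames are rejected", {
  st <- peartrack:::new_tracker_state(tracker_config())
  st <- step_tracker(st, make_dets(3L, 0, 0, 5, 5), 3L)
  expect_error(step_tracker(st, make_dets(2L, 0, 0, 5, 5), 2L),
               "increasing")
})

test_that("appearance mode requires embeddings", {
  t1 <- init_track(make_dets(0L, 0, 0, 10, 10, 1), 0L, 1L)
  t1$status <- "confirmed"
  expect_error(
    associate(list(predict_track(t1)), make_dets(1L, 0, 0, 10, 10, 1),
              tracker_config(cost_mode = "appearance")),
    "embedding")
})
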