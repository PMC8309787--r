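test_that("the learning-rate schedule ramps linearly then steps down", {
  s <- lr_schedule(lr0 = 0.001, warmup_iters = 1000, steps = c(4800, 5400),
                   d = 0.1, max_iter = 6000)
  expect_equal(lr_at(s, 2000), 0.001)   # plateau before the first step
  expect_equal(lr_at(s, 500), 0.0005)   # ramp midpoint
  expect_equal(lr_at(s, 5000), 1e-4)    # one decade after 4800
  expect_equal(lr_at(s, 5500), 1e-5)    # two decades after 5400
  expect_error(lr_at(s, 6500), "range")
  expect_error(lr_schedule(steps = c(5400, 4800)), "increasing")
  expect_error(lr_schedule(steps = c(500, 4800)), "warmup")
})

test_that("the schedule is continuous at warmup and non-increasing after", {
  s <- lr_schedule()
  tab <- lr_schedule_table(s)
  expect_equal(tab$lr[tab$iteration == s$warmup_iters], s$lr0)
  post <- tab$lr[tab$iteration >= s$warmup_iters]
  expect_true(all(diff(post) <= 0))
  # piecewise constant: only as many distinct values as decay segments
  expect_equal(length(unique(post)), length(s$steps) + 1L)
})

test_that("largest-remainder split sizes are exact on the full dataset", {
  n <- 1337L
  items <- data.frame(id = seq_len(n),
                      source = rep(c("highres", "phone"), c(1070, 267)))
  parts <- split_dataset(items, split_spec(seed = 3))
  expect_equal(vapply(parts, nrow, integer(1L)),
               c(train = 936L, train_val = 134L, val = 134L, test = 133L))
  # disjoint and exhaustive
  all_ids <- unname(unlist(lapply(parts, `[[`, "id")))
  expect_equal(sort(all_ids), seq_len(n))
  # source eligibility respected
  expect_true(all(parts$train$source == "highres"))
  expect_true(all(parts$train_val$source == "highres"))
  expect_true(all(parts$val$source == "phone"))
  expect_true(all(parts$test$source == "phone"))
})

test_that("augmentation groups never straddle partitions", {
  items <- data.frame(id = 1:40,
                      source = rep(c("highres", "phone"), c(32, 8)),
                      group = c(rep(1:8, each = 4), rep(9:10, each = 4)))
  parts <- split_dataset(items, split_spec(seed = 1))
  for (p in parts) {
    for (g in unique(p$group)) {
      expect_true(all(items$id[items$group == g] %in% p$id))
    }
  }
  # all members of one original stay together
  ten <- data.frame(id = 1:10, source = "highres", group = 1L)
  expect_error(split_dataset(ten, split_spec()), "phone")
})

test_that("splits are reproducible per seed and source shortfalls error", {
  items <- data.frame(id = 1:100,
                      source = rep(c("highres", "phone"), c(80, 20)))
  p1 <- split_dataset(items, split_spec(seed = 7))
  p2 <- split_dataset(items, split_spec(seed = 7))
  expect_identical(p1, p2)
  p3 <- split_dataset(items, split_spec(seed = 8))
  expect_false(identical(p1$train$id, p3$train$id))
  short <- data.frame(id = 1:100,
                      source = rep(c("highres", "phone"), c(95, 5)))
  expect_error(split_dataset(short, split_spec()), "phone-source shortfall")
})

test_that("split manifests are written as four plain-text id lists", {
  items <- data.frame(id = 1:100,
                      source = rep(c("highres", "phone"), c(80, 20)))
  parts <- split_dataset(items, split_spec(seed = 2))
  dir <- withr::local_tempdir()
  write_split_manifests(parts, dir)
  files <- file.path(dir, c("train.txt", "train_val.txt", "val.txt",
                            "test.txt"))
  expect_true(all(file.exists(files)))
  expect_equal(length(readLines(files[1])), nrow(parts$train))
})

test_that("k-means anchors recover trivial and well-separated clusters", {
  dims <- matrix(rep(c(10, 20), 6), ncol = 2, byrow = TRUE)
  a <- kmeans_anchors(dims, 1, seed = 1)
  expect_equal(unname(a[1, ]), c(10, 20))

  # two well-separated size clusters: compare against the brute-force
  # best 2-partition (exhaustive over all assignments, medoid centers)
  set.seed(4)
  small <- cbind(runif(5, 8, 12), runif(5, 8, 12))
  large <- cbind(runif(5, 80, 120), runif(5, 80, 120))
  dims <- rbind(small, large)
  a2 <- kmeans_anchors(dims, 2, seed = 2)
  cost_of <- function(centers) {
    d <- sapply(seq_len(nrow(centers)), function(j)
      1 - peartrack:::anchor_iou(dims[, 1], dims[, 2],
                                 centers[j, 1], centers[j, 2]))
    mean(apply(d, 1, min))
  }
  best <- Inf
  n <- nrow(dims)
  for (mask in 1:(2^n - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    medoid <- function(sub) {
      D <- 1 - outer(seq_len(nrow(sub)), seq_len(nrow(sub)), function(i, j)
        peartrack:::anchor_iou(sub[i, 1], sub[i, 2], sub[j, 1], sub[j, 2]))
      sub[which.min(rowSums(D)), ]
    }
    centers <- rbind(medoid(dims[g, , drop = FALSE]),
                     medoid(dims[!g, , drop = FALSE]))
    best <- min(best, cost_of(centers))
  }
  expect_equal(attr(a2, "cost"), best, tolerance = 1e-9)
  # sorted ascending by area
  expect_true(a2[1, 1] * a2[1, 2] < a2[2, 1] * a2[2, 2])
})

test_that("anchor clustering descends monotonically and is seed-stable", {
  set.seed(9)
  dims <- cbind(runif(60, 5, 120), runif(60, 5, 120))
  a1 <- kmeans_anchors(dims, 4, seed = 5)
  a2 <- kmeans_anchors(dims, 4, seed = 5)
  expect_identical(a1, a2)
  trace <- attr(a1, "cost_trace")
  expect_true(all(diff(trace) <= 1e-12))
  expect_error(kmeans_anchors(dims, 0, seed = 1), "k must")
  expect_error(kmeans_anchors(dims, 61, seed = 1), "k must")
})

test_that("the error-gap report reads staged AP progressions", {
  # an increasing AP pattern across the four-way split is all ok
  r <- error_gap_report(92.86, 92.86, 94.61, 96.64)
  expect_true(all(r$verdicts[c("B", "C", "D")] == "ok"))
  expect_true(is.na(r$verdicts["A"]))

  # a large train -> train-val drop flags overfitting
  r <- error_gap_report(95, 75, 74, 74)
  expect_equal(unname(r$verdicts["B"]), "overfit")

  # a large val -> test drop flags validation overfitting
  r <- error_gap_report(95, 94, 95, 80)
  expect_equal(unname(r$verdicts["D"]), "val_overfit")

  # data mismatch between training-source and deployment-source images
  r <- error_gap_report(95, 94, 70, 70)
  expect_equal(unname(r$verdicts["C"]), "data_mismatch")

  # stage A needs a target
  r <- error_gap_report(90, 90, 90, 90, target_ap = 99)
  expect_equal(unname(r$verdicts["A"]), "high_bias")
  expect_error(error_gap_report(120, 90, 90, 90), "percentages")
})
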