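# Training-methodology utilities: multi-step learning-rate decay with
# linear warmup, stratified four-way data splitting, IoU-distance k-means
# anchor clustering, and the staged error-gap report.

#' Learning-rate schedule: linear warmup + multi-step decay
#'
#' For the first `warmup_iters` iterations the rate ramps linearly from 0 to
#' `lr0` (reaching `lr0` exactly at `warmup_iters`); afterwards it is
#' piecewise constant, multiplied by `d` immediately after each step
#' iteration: `lr(n) = lr0 * d^(#steps strictly below n)`.
#'
#' @param lr0 initial learning rate (default 0.001).
#' @param warmup_iters warmup length in iterations (default 1000).
#' @param steps strictly increasing iteration indices at which the decay
#'   fires (default `c(4800, 5400)`); all must exceed `warmup_iters`.
#' @param d decay factor in (0, 1) (default 0.1).
#' @param max_iter last valid iteration (default 6000).
#' @return An `lr_schedule` list.
#' @export
lr_schedule <- function(lr0 = 0.001, warmup_iters = 1000L,
                        steps = c(4800L, 5400L), d = 0.1,
                        max_iter = 6000L) {
  steps <- as.integer(steps)
  stopifnot(lr0 > 0, warmup_iters >= 0L, d > 0, d < 1, max_iter > 0L)
  if (is.unsorted(steps, strictly = TRUE))
    stop("steps must be strictly increasing", call. = FALSE)
  if (length(steps) && any(steps <= warmup_iters))
    stop("all steps must lie beyond the warmup", call. = FALSE)
  structure(list(lr0 = lr0, warmup_iters = as.integer(warmup_iters),
                 steps = steps, d = d, max_iter = as.integer(max_iter)),
            class = "lr_schedule")
}

#' @rdname lr_schedule
#' @param schedule an `lr_schedule`.
#' @param n iteration index (vectorized), `0 <= n <= max_iter`.
#' @return `lr_at()`: the learning rate(s) at `n`.
#' @examples
#' s <- lr_schedule()
#' lr_at(s, c(500, 2000, 5000, 5500))  # 5e-4, 1e-3, 1e-4, 1e-5
#' @export
lr_at <- function(schedule, n) {
  if (any(n < 0) || any(n > schedule$max_iter))
    stop("iteration out of range [0, max_iter]", call. = FALSE)
  warm <- n < schedule$warmup_iters
  k <- vapply(n, function(ni) sum(schedule$steps < ni), numeric(1L))
  out <- schedule$lr0 * schedule$d^k
  if (schedule$warmup_iters > 0)
    out[warm] <- schedule$lr0 * n[warm] / schedule$warmup_iters
  out
}

#' @rdname lr_schedule
#' @return `lr_schedule_table()`: data.frame of (iteration, lr) over the
#'   whole schedule, for plotting.
#' @export
lr_schedule_table <- function(schedule) {
  it <- 0:schedule$max_iter
  data.frame(iteration = it, lr = lr_at(schedule, it))
}

#' Split specification for the four-way stratified split
#'
#' The dataset is split 70:10:10:10 into train, train-validation, validation
#' and test sets. High-resolution items are eligible for train/train-val
#' only; phone items for val/test only (the deployment camera differs from
#' the training camera, so the val/test sets must come from the deployment
#' source). Augmented derivatives of one original image never straddle
#' partitions.
#'
#' @param ratios `c(train, train_val, val, test)` summing to 1.
#' @param seed shuffle seed.
#' @return A `split_spec` list.
#' @export
split_spec <- function(ratios = c(0.70, 0.10, 0.10, 0.10), seed = 1L) {
  if (length(ratios) != 4L || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be 4 numbers summing to 1", call. = FALSE)
  structure(list(ratios = ratios, seed = as.integer(seed)),
            class = "split_spec")
}

# Largest-remainder apportionment of n into parts proportional to ratios;
# ties go to the earlier part.
largest_remainder <- function(n, ratios) {
  quota <- n * ratios
  sizes <- floor(quota)
  left <- n - sum(sizes)
  if (left > 0) {
    ord <- order(-(quota - sizes), seq_along(ratios))
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1
  }
  as.integer(sizes)
}

#' Four-way stratified, group-aware dataset split
#'
#' Target partition sizes come from largest-remainder rounding of the ratios
#' over the full set. Items are shuffled by seed at the level of their
#' original-image group (so augmented copies stay together), then
#' high-resolution groups fill train and train-val and phone groups fill val
#' and test. A source shortfall (e.g. too few phone items for val + test) is
#' an explicit error, never silently backfilled from the other source.
#'
#' @param items data.frame with columns `id`, `source` (`"highres"` or
#'   `"phone"`) and optionally `group` (original-image key; defaults to
#'   `id`).
#' @param spec a [split_spec].
#' @return Named list of four data.frames: `train`, `train_val`, `val`,
#'   `test`.
#' @export
split_dataset <- function(items, spec = split_spec()) {
  if (!all(c("id", "source") %in% names(items)))
    stop("items need columns id and source", call. = FALSE)
  if (!all(items$source %in% c("highres", "phone")))
    stop("source must be 'highres' or 'phone'", call. = FALSE)
  if (is.null(items$group)) items$group <- items$id
  sizes <- largest_remainder(nrow(items), spec$ratios)
  names(sizes) <- c("train", "train_val", "val", "test")

  n_high <- sum(items$source == "highres")
  n_phone <- sum(items$source == "phone")
  if (n_phone < sizes[["val"]] + sizes[["test"]])
    stop(sprintf(paste("phone-source shortfall: val+test need %d items but",
                       "only %d phone items are available"),
                 sizes[["val"]] + sizes[["test"]], n_phone), call. = FALSE)
  if (n_high < sizes[["train"]] + sizes[["train_val"]])
    stop(sprintf(paste("high-resolution shortfall: train+train-val need %d",
                       "items but only %d are available"),
                 sizes[["train"]] + sizes[["train_val"]], n_high),
         call. = FALSE)

  fill <- function(sub, targets, seed_offset) {
    groups <- unique(sub$group)
    groups <- with_seed(spec$seed + seed_offset, sample(groups))
    part <- setNames(vector("list", length(targets)), names(targets))
    gi <- 1L
    for (p in names(targets)) {
      taken <- 0L
      rows <- list()
      while (taken < targets[[p]] && gi <= length(groups)) {
        g <- sub[sub$group == groups[gi], , drop = FALSE]
        rows <- c(rows, list(g))
        taken <- taken + nrow(g)
        gi <- gi + 1L
      }
      part[[p]] <- if (length(rows)) do.call(rbind, rows) else sub[0, ]
    }
    # leftover groups join the last partition
    while (gi <= length(groups)) {
      part[[length(part)]] <- rbind(part[[length(part)]],
                                    sub[sub$group == groups[gi], ,
                                        drop = FALSE])
      gi <- gi + 1L
    }
    part
  }

  high <- fill(items[items$source == "highres", , drop = FALSE],
               sizes[c("train", "train_val")], 0L)
  phone <- fill(items[items$source == "phone", , drop = FALSE],
                sizes[c("val", "test")], 1L)
  out <- c(high, phone)
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  out
}

#' @rdname split_dataset
#' @param parts a split from [split_dataset()].
#' @param dir output directory; writes one plain-text id list per
#'   partition (`train.txt`, `train_val.txt`, `val.txt`, `test.txt`).
#' @export
write_split_manifests <- function(parts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(parts))
    writeLines(as.character(parts[[nm]]$id), file.path(dir,
                                                       paste0(nm, ".txt")))
  invisible(dir)
}

# IoU of two (w, h) boxes anchored at the origin.
anchor_iou <- function(w1, h1, w2, h2) {
  inter <- pmin(w1, w2) * pmin(h1, h2)
  inter / (w1 * h1 + w2 * h2 - inter)
}

#' k-means anchor clustering with 1 - IoU distance
#'
#' Clusters box dimensions with the YOLO anchor distance
#' `d(box, anchor) = 1 - IoU` (both boxes anchored at the origin), seeded
#' k-means++ initialization and medoid-style center updates (the cluster
#' member minimizing the summed distance), iterated to an assignment
#' fixpoint or `max_iter` rounds. Medoid updates make the mean cost
#' non-increasing across iterations.
#'
#' @param dims data.frame or matrix of box dimensions with columns `w`, `h`
#'   (or two unnamed columns).
#' @param k number of anchors; `1 <= k <= nrow(dims)`.
#' @param seed RNG seed for the initialization.
#' @param max_iter iteration cap (default 300).
#' @return Matrix of k anchor `(w, h)` pairs sorted ascending by area, with
#'   attributes `cost` (final mean 1 - IoU) and `cost_trace`.
#' @export
kmeans_anchors <- function(dims, k, seed = 1L, max_iter = 300L) {
  dims <- as.matrix(dims)[, 1:2, drop = FALSE]
  colnames(dims) <- c("w", "h")
  n <- nrow(dims)
  if (k <= 0 || k > n)
    stop("k must satisfy 1 <= k <= number of boxes", call. = FALSE)
  dist_to <- function(centers) {
    # n x k matrix of 1 - IoU
    1 - outer(seq_len(n), seq_len(nrow(centers)),
              function(i, j) anchor_iou(dims[i, 1L], dims[i, 2L],
                                        centers[j, 1L], centers[j, 2L]))
  }
  centers <- with_seed(seed, {
    idx <- sample.int(n, 1L)
    cent <- dims[idx, , drop = FALSE]
    while (nrow(cent) < k) {
      d2 <- apply(dist_to(cent), 1L, min)^2
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      cent <- rbind(cent, dims[sample.int(n, 1L, prob = probs), ])
    }
    cent
  })
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    D <- dist_to(centers)
    assign_new <- max.col(-D, ties.method = "first")
    trace <- c(trace, mean(D[cbind(seq_len(n), assign_new)]))
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      members <- which(assign_new == j)
      if (!length(members)) next
      sub <- dims[members, , drop = FALSE]
      Dm <- 1 - outer(seq_along(members), seq_along(members),
                      function(a, b) anchor_iou(sub[a, 1L], sub[a, 2L],
                                                sub[b, 1L], sub[b, 2L]))
      centers[j, ] <- sub[which.min(rowSums(Dm)), ]
    }
  }
  centers <- centers[order(centers[, 1L] * centers[, 2L]), , drop = FALSE]
  rownames(centers) <- NULL
  attr(centers, "cost") <- tail(trace, 1L)
  attr(centers, "cost_trace") <- trace
  centers
}

#' Staged error-gap report
#'
#' Reads the four-way split's average precisions as a staged diagnosis:
#' stage A (bias: train AP vs a user-supplied target), stage B (train vs
#' train-val: overfitting), stage C (train-val vs val: data mismatch between
#' the training-source and deployment-source images) and stage D (val vs
#' test: validation overfitting). A stage is `ok` when its downstream AP is
#' within `tolerance` percentage points of (or better than) its upstream AP.
#'
#' @param ap_train,ap_train_val,ap_val,ap_test average precisions in
#'   percent (0-100). `ap_train` may be `NA` when the training-set AP was
#'   not measured; stages that need it are then reported `NA`.
#' @param tolerance allowed unfavorable gap in percentage points
#'   (default 2).
#' @param target_ap optional stage-A target (e.g. 100 minus the human error
#'   rate); stage A is `NA` when absent.
#' @return A `gap_report` list with the four APs, per-stage gaps and
#'   verdicts (`ok`, `overfit`, `data_mismatch`, `val_overfit`, `high_bias`
#'   or `NA`).
#' @export
error_gap_report <- function(ap_train, ap_train_val, ap_val, ap_test,
                             tolerance = 2, target_ap = NULL) {
  aps <- c(train = ap_train, train_val = ap_train_val, val = ap_val,
           test = ap_test)
  if (any(aps < 0 | aps > 100, na.rm = TRUE))
    stop("average precisions must be percentages in [0, 100]", call. = FALSE)
  verdict <- function(gap, label) {
    if (is.na(gap)) NA_character_
    else if (gap <= tolerance) "ok"
    else label
  }
  gap_a <- if (is.null(target_ap) || is.na(ap_train)) NA_real_
           else target_ap - ap_train
  gap_b <- ap_train - ap_train_val
  gap_c <- ap_train_val - ap_val
  gap_d <- ap_val - ap_test
  structure(list(
    ap = aps, tolerance = tolerance,
    gaps = c(A = gap_a, B = gap_b, C = gap_c, D = gap_d),
    verdicts = c(A = verdict(gap_a, "high_bias"),
                 B = verdict(gap_b, "overfit"),
                 C = verdict(gap_c, "data_mismatch"),
                 D = verdict(gap_d, "val_overfit"))),
    class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report>\n")
  cat(sprintf("  AP: train %s  train-val %s  val %s  test %s\n",
              format(x$ap[1L]), format(x$ap[2L]), format(x$ap[3L]),
              format(x$ap[4L])))
  for (s in names(x$gaps))
    cat(sprintf("  stage %s: gap %s -> %s\n", s, format(x$gaps[[s]]),
                ifelse(is.na(x$verdicts[[s]]), "NA", x$verdicts[[s]])))
  invisible(x)
}
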