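# Scoring a count record against ground truth: CLEAR-MOT style counting
# metrics (MOTA with mismatches fixed at 0 for static fruit) and the
# false-negative breakdown by failure mode.

#' Match counted track ids to ground-truth objects
#'
#' Overlap between a track and an object is the mean IoU over their
#' co-visible frames. Counted ids are greedily assigned to distinct objects
#' in descending overlap; a pair is admissible when its overlap is at least
#' `min_track_iou`. Assigned ids are TP, unassigned counted ids FP,
#' unclaimed objects FN.
#'
#' @param record a `count_record`.
#' @param tracks the `track_set` the record was counted from (must contain
#'   every counted id).
#' @param gt a [gt_scene].
#' @param min_track_iou admissibility threshold on mean co-visible IoU
#'   (default 0.3).
#' @return List with `TP`, `FP`, `FN`, `tp_ids`, `fp_ids`, `fn_objects`
#'   (ground-truth ids missed), `assignment` (data.frame id -> object) and
#'   `id_switches` (diagnostic: extra admissible tracks per object beyond
#'   the first).
#' @export
match_counts_to_gt <- function(record, tracks, gt, min_track_iou = 0.3) {
  track_ids <- vapply(tracks, `[[`, integer(1L), "id")
  missing <- setdiff(record$counted_ids, track_ids)
  if (length(missing))
    stop("counted id(s) absent from tracks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  objs <- object_ids(gt)
  counted <- record$counted_ids
  if (!length(counted) || !length(objs)) {
    return(list(TP = 0L, FP = length(counted), FN = length(objs),
                tp_ids = integer(0), fp_ids = counted, fn_objects = objs,
                assignment = data.frame(id = integer(0), object = integer(0)),
                id_switches = 0L))
  }
  gt_by_obj <- split(gt$boxes, gt$boxes$id)
  overlap <- matrix(0, length(counted), length(objs),
                    dimnames = list(counted, objs))
  for (i in seq_along(counted)) {
    tr <- tracks[[which(track_ids == counted[i])]]
    h <- track_history_df(tr)
    for (j in seq_along(objs)) {
      g <- gt_by_obj[[as.character(objs[j])]]
      common <- intersect(h$frame, g$frame)
      if (!length(common)) next
      hi <- h[match(common, h$frame), ]
      gi <- g[match(common, g$frame), ]
      ious <- vapply(seq_along(common), function(k)
        iou(c(hi$x[k], hi$y[k], hi$w[k], hi$h[k]),
            c(gi$x[k], gi$y[k], gi$w[k], gi$h[k])), numeric(1L))
      overlap[i, j] <- mean(ious)
    }
  }
  admissible <- overlap >= min_track_iou
  ord <- order(-overlap)
  used_i <- rep(FALSE, length(counted)); used_j <- rep(FALSE, length(objs))
  asg_i <- integer(0); asg_j <- integer(0)
  for (k in ord) {
    j <- (k - 1L) %/% length(counted) + 1L
    i <- (k - 1L) %% length(counted) + 1L
    if (!admissible[i, j] || used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    asg_i <- c(asg_i, i); asg_j <- c(asg_j, j)
  }
  id_switches <- sum(pmax(colSums(admissible) - 1L, 0L))
  list(TP = length(asg_i), FP = sum(!used_i), FN = sum(!used_j),
       tp_ids = counted[asg_i], fp_ids = counted[!used_i],
       fn_objects = objs[!used_j],
       assignment = data.frame(id = counted[asg_i], object = objs[asg_j]),
       id_switches = as.integer(id_switches))
}

#' Counting metrics (CLEAR-MOT subset)
#'
#' Populates recall/precision/F1 and MOTA from counting TP/FP/FN:
#' `R = TP/(TP+FN)`, `P = TP/(TP+FP)`, `F1 = 2PR/(P+R)` and
#' `MOTA = 1 - (FN + FP + mismatches)/total_gt`. Two FP-rate conventions are
#' supported: `"gt"` (`FP/total_gt`, the convention under which
#' `MOTA = 1 - FN_rate - FP_rate` when mismatches are 0 — the default) and
#' `"complement"` (`1 - P`).
#'
#' @param TP,FP,FN non-negative integers with `TP + FN = total_gt`.
#' @param mismatches identity mismatches (default 0: the counted objects are
#'   static, only the camera moves).
#' @param total_gt total ground-truth object count.
#' @param fp_rate_convention `"gt"` or `"complement"`.
#' @return A `count_eval_report` with rates as proportions in \[0, 1\]
#'   (MOTA may be negative).
#' @export
counting_metrics <- function(TP, FP, FN, mismatches = 0L,
                             total_gt = TP + FN,
                             fp_rate_convention = c("gt", "complement")) {
  fp_rate_convention <- match.arg(fp_rate_convention)
  stopifnot(TP >= 0, FP >= 0, FN >= 0, mismatches >= 0)
  if (total_gt <= 0) stop("total_gt must be positive", call. = FALSE)
  if (TP + FN != total_gt)
    stop("TP + FN must equal total_gt", call. = FALSE)
  R <- TP / (TP + FN)
  if (TP + FP > 0) {
    P <- TP / (TP + FP)
  } else {
    warning("no positive counts: precision undefined, reported as 0")
    P <- 0
  }
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  FP_rate <- switch(fp_rate_convention, gt = FP / total_gt, complement = 1 - P)
  MOTA <- 1 - (FN + FP + mismatches) / total_gt
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN), mismatches = as.integer(mismatches),
                 total_gt = as.integer(total_gt),
                 R_count = R, FN_rate = 1 - R, P_count = P,
                 FP_rate = FP_rate, F1_count = F1, MOTA = MOTA,
                 fp_rate_convention = fp_rate_convention),
            class = "count_eval_report")
}

#' @rdname counting_metrics
#' @param P_count,R_count,FN_rate,FP_rate printed percentage rates from
#'   which to reproduce F1 and MOTA directly (all on the 0-100 scale);
#'   `counting_metrics_from_rates()` is the metric-identity form used when
#'   only rates, not raw counts, are available.
#' @export
counting_metrics_from_rates <- function(P_count, R_count, FN_rate = 100 - R_count,
                                        FP_rate, mismatches = 0) {
  if (mismatches != 0)
    stop("the rate-identity form assumes mismatches = 0", call. = FALSE)
  F1 <- if (P_count + R_count > 0)
    2 * P_count * R_count / (P_count + R_count) else 0
  MOTA <- 100 - (FN_rate + FP_rate)
  list(F1_count = F1, MOTA = MOTA)
}

#' @export
print.count_eval_report <- function(x, ...) {
  cat("<count_eval_report>\n")
  cat(sprintf("  TP %d  FP %d  FN %d  mismatches %d  total_gt %d\n",
              x$TP, x$FP, x$FN, x$mismatches, x$total_gt))
  cat(sprintf("  R %.2f%%  FN rate %.2f%%  P %.2f%%  FP rate %.2f%%\n",
              100 * x$R_count, 100 * x$FN_rate, 100 * x$P_count,
              100 * x$FP_rate))
  cat(sprintf("  F1 %.2f%%  MOTA %.2f%%\n", 100 * x$F1_count, 100 * x$MOTA))
  invisible(x)
}

#' Breakdown of ROI-line false-negative counts by failure mode
#'
#' Classifies each missed ground-truth object into exactly one category
#' based on where the detector actually saw it: `never_detected` (no
#' associated detection at all), `detected_only_after_line` (every
#' associated detection sits past the line in the flow direction),
#' `detected_near_line` (first detection within a band of
#' `band_fraction * frame_height` around the line — just before or while
#' crossing) or `detected_other`.
#'
#' @param fn_objects ground-truth ids missed by the ROI-line count
#'   (`fn_objects` from [match_counts_to_gt()]).
#' @param gt a [gt_scene].
#' @param dets the detection stream fed to the tracker; a detection is
#'   associated with an object when its IoU with the object's box on that
#'   frame is at least `iou_threshold`.
#' @param line_y ROI line height in pixels.
#' @param frame_height frame height in pixels.
#' @param band_fraction half-width of the near-line band as a fraction of
#'   frame height (default 0.05).
#' @param iou_threshold association threshold (default 0.5).
#' @param flow image flow direction: `"downward"` (objects move toward
#'   larger y, the default) or `"upward"`.
#' @return Named integer vector over the four categories; the categories
#'   partition the FN set.
#' @export
fn_breakdown <- function(fn_objects, gt, dets, line_y, frame_height,
                         band_fraction = 0.05, iou_threshold = 0.5,
                         flow = c("downward", "upward")) {
  flow <- match.arg(flow)
  out <- c(never_detected = 0L, detected_only_after_line = 0L,
           detected_near_line = 0L, detected_other = 0L)
  if (!length(fn_objects)) return(out)
  dets <- as_detections(as.data.frame(dets))
  det_by_frame <- split(dets, dets$frame)
  band <- band_fraction * frame_height
  for (obj in fn_objects) {
    g <- gt$boxes[gt$boxes$id == obj, , drop = FALSE]
    det_cy <- numeric(0); det_frames <- integer(0)
    for (r in seq_len(nrow(g))) {
      d <- det_by_frame[[as.character(g$frame[r])]]
      if (is.null(d) || !nrow(d)) next
      ious <- iou_matrix(as.matrix(g[r, c("x", "y", "w", "h")]),
                         as.matrix(d[c("x", "y", "w", "h")]))[1L, ]
      hit <- which(ious >= iou_threshold)
      if (length(hit)) {
        det_cy <- c(det_cy, d$y[hit] + d$h[hit] / 2)
        det_frames <- c(det_frames, rep(g$frame[r], length(hit)))
      }
    }
    cat_name <- if (!length(det_cy)) {
      "never_detected"
    } else {
      past <- if (flow == "downward") det_cy > line_y else det_cy < line_y
      first_cy <- det_cy[which.min(det_frames)]
      if (all(past)) "detected_only_after_line"
      else if (abs(first_cy - line_y) <= band) "detected_near_line"
      else "detected_other"
    }
    out[cat_name] <- out[cat_name] + 1L
  }
  out
}

#' Write a counting-evaluation comparison CSV
#'
#' Rows MOTA, FN rate, FP rate, Precision, Recall, F1 (percentages, 2
#' decimals) with one column per counting method.
#'
#' @param reports named list of `count_eval_report`s (names are the method
#'   columns).
#' @param path output csv.
#' @export
write_count_eval_report <- function(reports, path) {
  metric_rows <- c(MOTA = "MOTA", `FN rate` = "FN_rate",
                   `FP rate` = "FP_rate", Precision = "P_count",
                   Recall = "R_count", F1 = "F1_count")
  df <- data.frame(metric = names(metric_rows))
  for (nm in names(reports)) {
    r <- reports[[nm]]
    df[[nm]] <- vapply(metric_rows, function(f)
      round(100 * r[[f]], 2), numeric(1L))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
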