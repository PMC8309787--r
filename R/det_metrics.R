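# Pascal-VOC style detection evaluation: IoU-thresholded greedy matching,
# precision/recall/F1 and 11-point interpolated average precision.

#' Detection-evaluation configuration
#'
#' @param iou_threshold minimum IoU for a detection to claim a ground-truth
#'   box (default 0.5).
#' @param confidence_threshold detections below this confidence are suppressed
#'   before TP/FP/FN counting (default 0.25); suppressed detections leave
#'   their objects unclaimed (counted as FN) and are themselves neither TP
#'   nor FP.
#' @return An `eval_config` list.
#' @export
eval_config <- function(iou_threshold = 0.5, confidence_threshold = 0.25) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must lie in (0, 1]", call. = FALSE)
  if (confidence_threshold < 0 || confidence_threshold > 1)
    stop("confidence_threshold must lie in [0, 1]", call. = FALSE)
  structure(list(iou_threshold = iou_threshold,
                 confidence_threshold = confidence_threshold),
            class = "eval_config")
}

# Greedy single-claim matching of detections (in descending confidence, ties
# by (frame, left, top) via the detections ordering) against ground-truth
# boxes of the same frame: a detection claims the highest-IoU unclaimed box
# with IoU >= threshold. Returns, in detection order, the matched gt row (NA
# for unmatched) and the match IoU.
match_frame_greedy <- function(det_boxes, gt_boxes, iou_threshold) {
  nd <- nrow(det_boxes); ng <- nrow(gt_boxes)
  matched <- rep(NA_integer_, nd)
  match_iou <- rep(NA_real_, nd)
  if (nd == 0L || ng == 0L) return(list(matched = matched, iou = match_iou))
  M <- iou_matrix(det_boxes, gt_boxes)
  claimed <- rep(FALSE, ng)
  for (i in seq_len(nd)) {
    cand <- which(!claimed & M[i, ] >= iou_threshold)
    if (!length(cand)) next
    j <- cand[which.max(M[i, cand])]
    claimed[j] <- TRUE
    matched[i] <- j
    match_iou[i] <- M[i, j]
  }
  list(matched = matched, iou = match_iou)
}

#' Evaluate a detection stream against ground truth
#'
#' Per frame, detections below the confidence threshold are suppressed, the
#' survivors are greedily matched in descending confidence to ground-truth
#' boxes (single claim, IoU at or above the threshold, highest-IoU unclaimed
#' box wins). Matched detections are TP, unmatched ones FP, unclaimed
#' ground-truth boxes FN. Average precision is computed from a full
#' confidence sweep over all detections (no confidence suppression) with the
#' 11-point interpolation rule.
#'
#' @param dets a [detections] stream.
#' @param gt a [gt_scene]; detections on frames beyond the scene are an error
#'   (unless the scene is empty, in which case everything is FP).
#' @param cfg an [eval_config].
#' @return A `det_eval_report` list with fields `TP`, `FP`, `FN`, `P`, `R`,
#'   `F1`, `FNR`, `FPR`, `avg_iou`, `AP` (all rates as proportions in
#'   \[0, 1\]).
#' @export
evaluate_detections <- function(dets, gt, cfg = eval_config()) {
  dets <- as_detections(as.data.frame(dets))
  if (!inherits(gt, "gt_scene")) stop("gt must be a gt_scene", call. = FALSE)
  if (nrow(gt$boxes) && nrow(dets) && any(dets$frame >= gt$n_frames))
    stop("detection frames extend beyond the ground-truth scene",
         call. = FALSE)

  gt_by_frame <- split(gt$boxes, gt$boxes$frame)
  kept <- dets[dets$conf >= cfg$confidence_threshold, , drop = FALSE]
  det_by_frame <- if (nrow(kept)) split(kept, kept$frame) else list()

  frames <- sort(unique(c(as.integer(names(gt_by_frame)),
                          as.integer(names(det_by_frame)))))
  TP <- 0L; FP <- 0L; FN <- 0L
  tp_ious <- numeric(0)
  for (f in frames) {
    g <- gt_by_frame[[as.character(f)]]
    d <- det_by_frame[[as.character(f)]]
    ng <- if (is.null(g)) 0L else nrow(g)
    nd <- if (is.null(d)) 0L else nrow(d)
    if (nd) {
      m <- match_frame_greedy(as.matrix(d[c("x", "y", "w", "h")]),
                              if (ng) as.matrix(g[c("x", "y", "w", "h")])
                              else matrix(numeric(0), 0, 4),
                              cfg$iou_threshold)
      tp_f <- sum(!is.na(m$matched))
      TP <- TP + tp_f
      FP <- FP + (nd - tp_f)
      FN <- FN + (ng - tp_f)
      tp_ious <- c(tp_ious, m$iou[!is.na(m$matched)])
    } else {
      FN <- FN + ng
    }
  }

  labels <- label_detections_sweep(dets, gt, cfg$iou_threshold)
  n_gt <- nrow(gt$boxes)
  AP <- average_precision_11pt(labels, n_gt)

  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(list(TP = TP, FP = FP, FN = FN, P = P, R = R, F1 = F1,
                 FNR = 1 - R, FPR = 1 - P,
                 avg_iou = if (length(tp_ious)) mean(tp_ious) else 0,
                 AP = AP),
            class = "det_eval_report")
}

# TP/FP labels for the AP sweep: all detections ranked by descending
# confidence globally, greedy single-claim matching within each frame.
label_detections_sweep <- function(dets, gt, iou_threshold) {
  if (!nrow(dets)) return(logical(0))
  ord <- order(-dets$conf, dets$frame, dets$x, dets$y)
  d <- dets[ord, , drop = FALSE]
  gt_by_frame <- split(gt$boxes, gt$boxes$frame)
  claimed <- lapply(gt_by_frame, function(g) rep(FALSE, nrow(g)))
  is_tp <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    key <- as.character(d$frame[i])
    g <- gt_by_frame[[key]]
    if (is.null(g)) next
    free <- !claimed[[key]]
    if (!any(free)) next
    ious <- iou_matrix(as.matrix(d[i, c("x", "y", "w", "h")]),
                       as.matrix(g[c("x", "y", "w", "h")]))[1L, ]
    cand <- which(free & ious >= iou_threshold)
    if (!length(cand)) next
    j <- cand[which.max(ious[cand])]
    claimed[[key]][j] <- TRUE
    is_tp[i] <- TRUE
  }
  is_tp
}

#' 11-point interpolated average precision
#'
#' `AP = (1/11) * sum over r in {0, 0.1, ..., 1} of max(P at recall >= r)`,
#' with the maximum over an empty set taken as 0.
#'
#' @param is_tp logical TP/FP labels of the ranked detections, in descending
#'   confidence order.
#' @param n_gt number of ground-truth boxes.
#' @return AP in \[0, 1\].
#' @examples
#' average_precision_11pt(c(TRUE, FALSE, TRUE), n_gt = 2)  # 28/33
#' @export
average_precision_11pt <- function(is_tp, n_gt) {
  if (n_gt < 0) stop("n_gt must be >= 0", call. = FALSE)
  if (n_gt == 0L) {
    if (length(is_tp)) warning("no ground-truth boxes: AP defined as 0")
    return(0)
  }
  if (!length(is_tp)) return(0)
  cum_tp <- cumsum(as.logical(is_tp))
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(cum_tp)
  pts <- seq(0, 1, by = 0.1)
  interp <- vapply(pts, function(r) {
    sel <- recall >= r - 1e-12
    if (any(sel)) max(precision[sel]) else 0
  }, numeric(1L))
  mean(interp)
}

#' @export
print.det_eval_report <- function(x, ...) {
  cat("<det_eval_report>\n")
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$TP, x$FP, x$FN))
  cat(sprintf("  P %.4f  R %.4f  F1 %.4f  FNR %.4f  FPR %.4f\n",
              x$P, x$R, x$F1, x$FNR, x$FPR))
  cat(sprintf("  avg IoU %.4f  AP(11pt) %.4f\n", x$avg_iou, x$AP))
  invisible(x)
}

#' Write detection-evaluation reports as a flat CSV
#'
#' One row per run with columns TP, FP, FN, P, FPR, R, FNR, F1, avg_iou, AP;
#' rates are written as percentages rounded to 2 decimals.
#'
#' @param reports a named list of `det_eval_report`s (names become the `run`
#'   column), or a single report.
#' @param path output csv.
#' @export
write_det_report <- function(reports, path) {
  if (inherits(reports, "det_eval_report")) reports <- list(run = reports)
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(run = nm, TP = r$TP, FP = r$FP, FN = r$FN,
               P = round(100 * r$P, 2), FPR = round(100 * r$FPR, 2),
               R = round(100 * r$R, 2), FNR = round(100 * r$FNR, 2),
               F1 = round(100 * r$F1, 2),
               avg_iou = round(100 * r$avg_iou, 2),
               AP = round(100 * r$AP, 2))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
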