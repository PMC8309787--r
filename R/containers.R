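#' Per-frame detection stream
#'
#' A `detections` object is a data.frame with one row per detection and
#' columns `frame` (0-based integer), `x`, `y`, `w`, `h` (pixel box, left/top/
#' width/height), `conf` (confidence in \[0, 1\]) and optionally `embedding`
#' (a list column of unit-norm appearance vectors) and `source_id`
#' (simulator-only provenance: which true object produced the detection,
#' `NA` for spurious ones). Rows are kept sorted by frame and, within a
#' frame, by descending confidence.
#'
#' @param frame 0-based integer frame indices.
#' @param x,y,w,h pixel boxes (left, top, width, height).
#' @param conf confidences in \[0, 1\].
#' @param embedding optional list of numeric unit-norm vectors (or `NULL`
#'   entries), one per detection.
#' @param source_id optional integer provenance ids.
#' @return A `detections` data.frame.
#' @examples
#' detections(frame = c(0, 0), x = c(1, 5), y = c(2, 6),
#'            w = c(3, 3), h = c(4, 4), conf = c(0.9, 0.8))
#' @export
detections <- function(frame = integer(), x = numeric(), y = numeric(),
                       w = numeric(), h = numeric(), conf = numeric(),
                       embedding = NULL, source_id = NULL) {
  d <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                  y = as.numeric(y), w = as.numeric(w), h = as.numeric(h),
                  conf = as.numeric(conf))
  if (!is.null(embedding)) d$embedding <- I(embedding)
  if (!is.null(source_id)) d$source_id <- as.integer(source_id)
  as_detections(d)
}

#' @rdname detections
#' @param d a data.frame with at least the columns frame, x, y, w, h, conf.
#' @export
as_detections <- function(d) {
  needed <- c("frame", "x", "y", "w", "h", "conf")
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop("detections are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  validate_detections(d)
  ord <- order(d$frame, -d$conf, d$x, d$y)
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("detections", "data.frame")
  d
}

validate_detections <- function(d) {
  if (nrow(d) == 0L) return(invisible(d))
  if (any(d$frame < 0L)) stop("frame indices must be >= 0", call. = FALSE)
  if (any(d$w <= 0) || any(d$h <= 0))
    stop("detection boxes must have positive width and height", call. = FALSE)
  if (any(d$conf < 0 | d$conf > 1))
    stop("detection confidences must lie in [0, 1]", call. = FALSE)
  if (!is.null(d$embedding)) {
    ok <- vapply(d$embedding, function(e) {
      is.null(e) || abs(sqrt(sum(e^2)) - 1) <= 1e-6
    }, logical(1L))
    if (!all(ok))
      stop("appearance embeddings must have unit Euclidean norm (within 1e-6)",
           call. = FALSE)
  }
  invisible(d)
}

#' @export
print.detections <- function(x, n = 6L, ...) {
  cat(sprintf("<detections> %d detections over %d frame(s)\n", nrow(x),
              length(unique(x$frame))))
  cols <- setdiff(names(x), "embedding")
  print.data.frame(head(as.data.frame(x)[cols], n), ...)
  if (nrow(x) > n) cat(sprintf("# ... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Ground-truth scene
#'
#' Per-object, per-frame ground-truth boxes: the reference for both detection
#' and counting evaluation. Stored as a long data.frame of visible boxes
#' (columns `id`, `frame`, `x`, `y`, `w`, `h`) plus the frame size in pixels
#' and the number of frames.
#'
#' @param boxes data.frame with columns id, frame (0-based), x, y, w, h; one
#'   row per visible object-frame.
#' @param frame_size `c(width, height)` in pixels, or `NULL` to infer the
#'   smallest frame covering every box.
#' @param n_frames total frame count, or `NULL` to infer `max(frame) + 1`.
#' @return A `gt_scene` object.
#' @export
gt_scene <- function(boxes = data.frame(id = integer(), frame = integer(),
                                        x = numeric(), y = numeric(),
                                        w = numeric(), h = numeric()),
                     frame_size = NULL, n_frames = NULL) {
  needed <- c("id", "frame", "x", "y", "w", "h")
  missing <- setdiff(needed, names(boxes))
  if (length(missing))
    stop("ground-truth boxes are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  boxes <- boxes[needed]
  boxes$id <- as.integer(boxes$id)
  boxes$frame <- as.integer(boxes$frame)
  if (anyDuplicated(boxes[c("frame", "id")]))
    stop("duplicate (frame, id) pair in ground truth", call. = FALSE)
  if (nrow(boxes) && (any(boxes$w <= 0) || any(boxes$h <= 0)))
    stop("ground-truth boxes must have positive width and height",
         call. = FALSE)
  if (is.null(frame_size)) {
    frame_size <- if (nrow(boxes))
      c(ceiling(max(boxes$x + boxes$w)), ceiling(max(boxes$y + boxes$h)))
    else c(0, 0)
  }
  frame_size <- as.numeric(frame_size)
  if (nrow(boxes)) {
    # clip to the frame; drop boxes that end up degenerate
    x1 <- pmin(boxes$x + boxes$w, frame_size[1L]); x0 <- pmax(boxes$x, 0)
    y1 <- pmin(boxes$y + boxes$h, frame_size[2L]); y0 <- pmax(boxes$y, 0)
    keep <- x1 > x0 & y1 > y0
    boxes <- boxes[keep, , drop = FALSE]
    boxes$x <- x0[keep]; boxes$y <- y0[keep]
    boxes$w <- (x1 - x0)[keep]; boxes$h <- (y1 - y0)[keep]
  }
  if (is.null(n_frames))
    n_frames <- if (nrow(boxes)) max(boxes$frame) + 1L else 0L
  boxes <- boxes[order(boxes$frame, boxes$id), , drop = FALSE]
  rownames(boxes) <- NULL
  structure(list(boxes = boxes, frame_size = frame_size,
                 n_frames = as.integer(n_frames)),
            class = "gt_scene")
}

#' @rdname gt_scene
#' @param scene a `gt_scene`.
#' @export
n_objects <- function(scene) length(unique(scene$boxes$id))

#' @rdname gt_scene
#' @export
object_ids <- function(scene) sort(unique(scene$boxes$id))

#' @export
print.gt_scene <- function(x, ...) {
  cat(sprintf("<gt_scene> %d object(s), %d frame(s), frame %g x %g px\n",
              n_objects(x), x$n_frames, x$frame_size[1L], x$frame_size[2L]))
  invisible(x)
}
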