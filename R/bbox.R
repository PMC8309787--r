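#' Axis-aligned bounding box
#'
#' Boxes are numeric vectors `c(x, y, w, h)` in pixels: `x`/`y` are the left
#' and top edges (origin top-left, y downward), `w`/`h` the width and height.
#'
#' @param x,y left and top edge, pixels.
#' @param w,h width and height, pixels; must be positive.
#' @return Named numeric vector of class `bbox`.
#' @examples
#' b <- bbox(10, 20, 30, 40)
#' bbox_centroid(b)
#' @export
bbox <- function(x, y, w, h) {
  b <- c(x = as.numeric(x), y = as.numeric(y),
         w = as.numeric(w), h = as.numeric(h))
  validate_bbox(b)
  class(b) <- "bbox"
  b
}

validate_bbox <- function(b) {
  if (length(b) != 4L || anyNA(b) || !is.numeric(b))
    stop("a bounding box must be 4 finite numbers (x, y, w, h)", call. = FALSE)
  if (b[[3L]] <= 0 || b[[4L]] <= 0)
    stop("bounding box width and height must be positive", call. = FALSE)
  invisible(b)
}

#' @rdname bbox
#' @param box a box (`c(x, y, w, h)`).
#' @export
bbox_centroid <- function(box) {
  c(cx = box[[1L]] + box[[3L]] / 2, cy = box[[2L]] + box[[4L]] / 2)
}

#' Intersection over union of two boxes
#'
#' The ratio of the overlap area to the combined area of two axis-aligned
#' boxes; 0 when they are disjoint, 1 when identical.
#'
#' @param a,b boxes as `c(x, y, w, h)` numeric vectors.
#' @return A number in \[0, 1\].
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 10, 10))  # 1/3
#' @export
iou <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  ix <- min(a[[1L]] + a[[3L]], b[[1L]] + b[[3L]]) - max(a[[1L]], b[[1L]])
  iy <- min(a[[2L]] + a[[4L]], b[[2L]] + b[[4L]]) - max(a[[2L]], b[[2L]])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a[[3L]] * a[[4L]] + b[[3L]] * b[[4L]] - inter)
}

# Vectorized IoU between every row of A and every row of B.
# A, B: matrices with columns x, y, w, h. Returns nrow(A) x nrow(B).
iou_matrix <- function(A, B) {
  if (!is.matrix(A)) A <- matrix(A, ncol = 4L)
  if (!is.matrix(B)) B <- matrix(B, ncol = 4L)
  m <- nrow(A); n <- nrow(B)
  if (m == 0L || n == 0L) return(matrix(numeric(0), m, n))
  ax0 <- A[, 1L]; ay0 <- A[, 2L]; ax1 <- ax0 + A[, 3L]; ay1 <- ay0 + A[, 4L]
  bx0 <- B[, 1L]; by0 <- B[, 2L]; bx1 <- bx0 + B[, 3L]; by1 <- by0 + B[, 4L]
  ix <- outer(ax1, bx1, pmin) - outer(ax0, bx0, pmax)
  iy <- outer(ay1, by1, pmin) - outer(ay0, by0, pmax)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  areas <- outer(A[, 3L] * A[, 4L], B[, 3L] * B[, 4L], `+`)
  inter / (areas - inter)
}
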