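# Readers/writers for the MOT-challenge and YOLO/Darknet text dialects.
# One internal convention everywhere: pixels, origin top-left, boxes as
# (left, top, width, height), frames 0-based (MOT files are 1-based on disk).

fmt_num <- function(v) {
  vapply(v, function(x) {
    if (is.finite(x) && x == round(x)) sprintf("%d", as.integer(round(x)))
    else formatC(x, format = "g", digits = 10)
  }, character(1L))
}

split_fields <- function(lines, sep, path) {
  parts <- strsplit(lines, sep)
  parts
}

parse_numeric_field <- function(s, path, line_no) {
  v <- suppressWarnings(as.numeric(s))
  if (anyNA(v))
    stop(sprintf("malformed line %d in '%s'", line_no, path), call. = FALSE)
  v
}

#' Read a detection stream
#'
#' Reads per-frame bounding-box detections from either the MOT-challenge
#' `det.txt` dialect (CSV lines `frame,id,bb_left,bb_top,bb_width,bb_height,
#' conf,...`, frames 1-based on disk) or a directory of YOLO/Darknet per-frame
#' annotation files (lines `class cx cy w h [conf]`, all normalized to
#' \[0, 1\]). Class ids in YOLO files are ignored (single-class streams).
#'
#' @param path file (`mot-det`) or directory of `.txt` files (`yolo-dir`).
#' @param dialect `"mot-det"` or `"yolo-dir"`.
#' @param frame_size `c(width, height)` in pixels; required for `yolo-dir`
#'   (or provided by a one-line `frame_size.txt` sidecar in the directory).
#' @return A [detections] data.frame sorted by (frame, descending confidence).
#' @export
read_detections <- function(path, dialect = c("mot-det", "yolo-dir"),
                            frame_size = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "mot-det") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(detections())
    parts <- strsplit(lines, ",")
    n_fields <- lengths(parts)
    if (any(n_fields < 7L))
      stop(sprintf("malformed line %d in '%s'", which(n_fields < 7L)[1L], path),
           call. = FALSE)
    rows <- lapply(seq_along(parts), function(i)
      parse_numeric_field(parts[[i]][1:7], path, i))
    m <- do.call(rbind, rows)
    if (any(m[, 1L] < 1))
      stop("MOT frame indices must be >= 1 on disk", call. = FALSE)
    detections(frame = m[, 1L] - 1, x = m[, 3L], y = m[, 4L],
               w = m[, 5L], h = m[, 6L], conf = m[, 7L])
  } else {
    if (!dir.exists(path))
      stop(sprintf("'%s' is not a directory", path), call. = FALSE)
    if (is.null(frame_size)) {
      sidecar <- file.path(path, "frame_size.txt")
      if (file.exists(sidecar))
        frame_size <- scan(sidecar, quiet = TRUE, n = 2)
      else
        stop("the yolo-dir dialect needs a frame_size (argument or ",
             "frame_size.txt sidecar)", call. = FALSE)
    }
    W <- frame_size[1L]; H <- frame_size[2L]
    files <- sort(setdiff(list.files(path, pattern = "\\.txt$"),
                          "frame_size.txt"))
    out <- vector("list", length(files))
    for (k in seq_along(files)) {
      lines <- readLines(file.path(path, files[k]))
      lines <- lines[nzchar(trimws(lines))]
      if (!length(lines)) next
      parts <- strsplit(trimws(lines), "[[:space:]]+")
      n_fields <- lengths(parts)
      if (any(n_fields < 5L | n_fields > 6L))
        stop(sprintf("malformed line %d in '%s'",
                     which(n_fields < 5L | n_fields > 6L)[1L], files[k]),
             call. = FALSE)
      rows <- lapply(seq_along(parts), function(i) {
        v <- parse_numeric_field(parts[[i]][-1L], files[k], i)
        if (length(v) == 4L) v <- c(v, 1)
        v
      })
      m <- do.call(rbind, rows)
      out[[k]] <- data.frame(frame = k - 1L,
                             x = (m[, 1L] - m[, 3L] / 2) * W,
                             y = (m[, 2L] - m[, 4L] / 2) * H,
                             w = m[, 3L] * W, h = m[, 4L] * H,
                             conf = m[, 5L])
    }
    out <- out[!vapply(out, is.null, logical(1L))]
    if (!length(out)) return(detections())
    as_detections(do.call(rbind, out))
  }
}

#' Write a detection stream
#'
#' Writes the MOT-challenge `det.txt` dialect (frames re-based to 1 on disk,
#' placeholder id -1). `write_detections()` then [read_detections()] is the
#' identity on the stream.
#'
#' @param dets a [detections] data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path) {
  dets <- as_detections(as.data.frame(dets))
  lines <- sprintf("%d,-1,%s,%s,%s,%s,%s,-1,-1,-1",
                   dets$frame + 1L, fmt_num(dets$x), fmt_num(dets$y),
                   fmt_num(dets$w), fmt_num(dets$h), fmt_num(dets$conf))
  writeLines(lines, path)
  invisible(path)
}

#' Read ground-truth trajectories
#'
#' Reads the MOT-challenge `gt.txt` dialect: CSV lines
#' `frame,id,bb_left,bb_top,bb_width,bb_height,flag,...` with 1-based frames;
#' rows with flag 0 are treated as not visible. Duplicate (frame, id) pairs
#' are an error.
#'
#' @param path gt file.
#' @param dialect only `"mot-gt"`.
#' @param frame_size optional `c(width, height)` pixels; inferred from box
#'   extents when absent.
#' @return A [gt_scene].
#' @export
read_ground_truth <- function(path, dialect = "mot-gt", frame_size = NULL) {
  dialect <- match.arg(dialect, "mot-gt")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gt_scene(frame_size = frame_size, n_frames = 0L))
  parts <- strsplit(lines, ",")
  n_fields <- lengths(parts)
  if (any(n_fields < 7L))
    stop(sprintf("malformed line %d in '%s'", which(n_fields < 7L)[1L], path),
         call. = FALSE)
  m <- do.call(rbind, lapply(seq_along(parts), function(i)
    parse_numeric_field(parts[[i]][1:7], path, i)))
  if (anyDuplicated(m[, 1:2, drop = FALSE]))
    stop("duplicate (frame, id) pair in ground truth", call. = FALSE)
  n_frames <- as.integer(max(m[, 1L]))
  keep <- m[, 7L] != 0
  m <- m[keep, , drop = FALSE]
  gt_scene(data.frame(id = m[, 2L], frame = m[, 1L] - 1, x = m[, 3L],
                      y = m[, 4L], w = m[, 5L], h = m[, 6L]),
           frame_size = frame_size, n_frames = n_frames)
}

#' @rdname read_ground_truth
#' @param scene a [gt_scene] to write in the `gt.txt` dialect.
#' @export
write_ground_truth <- function(scene, path) {
  b <- scene$boxes
  lines <- sprintf("%d,%d,%s,%s,%s,%s,1,-1,-1,-1",
                   b$frame + 1L, b$id, fmt_num(b$x), fmt_num(b$y),
                   fmt_num(b$w), fmt_num(b$h))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write appearance-embedding sidecars
#'
#' CSV with columns `frame` (1-based on disk), `det_index` (position of the
#' detection within its frame, in file order) and `v1..vd` vector components.
#' `read_embeddings()` attaches the vectors to a detection stream by
#' (frame, index) and renormalizes nothing: vectors are stored unit-norm.
#'
#' @param dets a [detections] data.frame.
#' @param path csv path.
#' @return `write_embeddings()`: `path`; `read_embeddings()`: `dets` with an
#'   `embedding` list column.
#' @export
write_embeddings <- function(dets, path) {
  if (is.null(dets$embedding)) stop("no embeddings to write", call. = FALSE)
  idx <- stats::ave(seq_len(nrow(dets)), dets$frame, FUN = seq_along)
  mat <- do.call(rbind, lapply(dets$embedding, function(e)
    if (is.null(e)) stop("embedding missing for a detection", call. = FALSE)
    else as.numeric(e)))
  df <- data.frame(frame = dets$frame + 1L, det_index = idx)
  colnames(mat) <- paste0("v", seq_len(ncol(mat)))
  utils::write.csv(cbind(df, mat), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(dets, path) {
  df <- utils::read.csv(path)
  idx <- stats::ave(seq_len(nrow(dets)), dets$frame, FUN = seq_along)
  key_d <- paste(dets$frame + 1L, idx)
  key_e <- paste(df$frame, df$det_index)
  pos <- match(key_d, key_e)
  if (anyNA(pos))
    stop("embedding sidecar does not cover every detection", call. = FALSE)
  vecs <- as.matrix(df[grep("^v[0-9]+$", names(df))])
  dets$embedding <- I(lapply(pos, function(p) as.numeric(vecs[p, ])))
  validate_detections(dets)
  dets
}
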