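# The two counting strategies over tracker output — ROI-line crossing and
# unique-ID counting — plus the lifespan-coverage filtered variant.

#' Counter configuration
#'
#' @param roi_fraction the ROI line sits at `roi_fraction * frame_height`
#'   (default 0.5, i.e. mid-frame).
#' @param direction crossing direction filter: `"any"` (default),
#'   `"downward"` (centroid y increasing through the line) or `"upward"`.
#' @param lifespan_fraction minimum fraction of a track's lifespan
#'   (first to last detected frame) that must carry detections for the
#'   lifespan-filtered count (default 0.8, boundary included).
#' @param count_only_confirmed count only tracks that were ever confirmed
#'   (default TRUE).
#' @return A `counter_config` list.
#' @export
counter_config <- function(roi_fraction = 0.5,
                           direction = c("any", "downward", "upward"),
                           lifespan_fraction = 0.8,
                           count_only_confirmed = TRUE) {
  direction <- match.arg(direction)
  stopifnot(roi_fraction > 0, roi_fraction < 1,
            lifespan_fraction >= 0, lifespan_fraction <= 1)
  structure(list(roi_fraction = roi_fraction, direction = direction,
                 lifespan_fraction = lifespan_fraction,
                 count_only_confirmed = isTRUE(count_only_confirmed)),
            class = "counter_config")
}

new_count_record <- function(method, counted_ids, crossing_frame = NULL) {
  structure(list(method = method, counted_ids = as.integer(counted_ids),
                 crossing_frame = crossing_frame,
                 total = length(counted_ids)),
            class = "count_record")
}

#' @export
print.count_record <- function(x, ...) {
  cat(sprintf("<count_record> method %s: total %d\n", x$method, x$total))
  invisible(x)
}

qualifying_tracks <- function(tracks, cfg) {
  if (!cfg$count_only_confirmed) return(tracks)
  tracks[vapply(tracks, `[[`, logical(1L), "ever_confirmed")]
}

#' Unique-ID counting
#'
#' Counts the distinct track identifiers the tracker emitted; each
#' qualifying id is counted exactly once.
#'
#' @param tracks a `track_set` from [run_tracker()].
#' @param cfg a [counter_config].
#' @return A `count_record` with method `"unique_id"`.
#' @export
count_unique_ids <- function(tracks, cfg = counter_config()) {
  ids <- sort(vapply(qualifying_tracks(tracks, cfg), `[[`, integer(1L), "id"))
  new_count_record("unique_id", ids)
}

# First frame at which the centroid-y series crosses line_y, or NA.
# A centroid exactly on the line crosses on the next off-line frame.
first_crossing <- function(frames, cy, line_y, direction) {
  s <- sign(cy - line_y)
  prev <- 0
  for (i in seq_along(s)) {
    if (s[i] == 0) next                 # on the line: defer to next frame
    if (prev != 0 && s[i] != prev) {
      ok <- switch(direction,
                   any = TRUE,
                   downward = prev < 0 && s[i] > 0,
                   upward = prev > 0 && s[i] < 0)
      if (ok) return(frames[i])
    }
    prev <- s[i]
  }
  NA_integer_
}

#' ROI-line counting
#'
#' A horizontal line is placed at `roi_fraction * frame_height`; a track is
#' counted at the first frame where its centroid crosses the line between
#' consecutive history frames (predicted-only frames included, so the
#' tracker bridges detector flicker). Each id is counted at most once no
#' matter how often it re-crosses.
#'
#' @param tracks a `track_set`.
#' @param frame_height frame height in pixels.
#' @param cfg a [counter_config].
#' @return A `count_record` with method `"roi_line"` and per-id crossing
#'   frames.
#' @export
count_roi_line <- function(tracks, frame_height, cfg = counter_config()) {
  if (frame_height <= 0) stop("frame_height must be positive", call. = FALSE)
  line_y <- cfg$roi_fraction * frame_height
  counted <- integer(0)
  crossing <- integer(0)
  for (tr in qualifying_tracks(tracks, cfg)) {
    h <- track_history_df(tr)
    cy <- h$y + h$h / 2
    f <- first_crossing(h$frame, cy, line_y, cfg$direction)
    if (!is.na(f)) {
      counted <- c(counted, tr$id)
      crossing <- c(crossing, f)
    }
  }
  ord <- order(counted)
  new_count_record("roi_line", counted[ord],
                   stats::setNames(crossing[ord], counted[ord]))
}

#' Lifespan-filtered unique-ID counting
#'
#' Counts a confirmed track only when it carried detections on at least
#' `lifespan_fraction` of its lifespan (frames between its first and last
#' detection, inclusive); a remedy for flicker-born fragment tracks.
#'
#' @inheritParams count_unique_ids
#' @return A `count_record` with method `"unique_id_lifespan"`.
#' @export
count_lifespan_filtered <- function(tracks, cfg = counter_config()) {
  ids <- integer(0)
  for (tr in qualifying_tracks(tracks, cfg)) {
    if (track_coverage(tr) >= cfg$lifespan_fraction) ids <- c(ids, tr$id)
  }
  new_count_record("unique_id_lifespan", sort(ids))
}

#' @rdname count_lifespan_filtered
#' @param track a single `track`; returns the fraction of its lifespan
#'   frames that had a detection.
#' @export
track_coverage <- function(track) {
  had <- vapply(track$history, `[[`, logical(1L), "had_detection")
  span <- track$last_frame - track$first_frame + 1L
  sum(had) / span
}

#' Write count records as CSV
#'
#' One row per method: `method,total,ids` (ids semicolon-separated), plus a
#' companion `<path>_crossings.csv` with per-id crossing frames when an
#' ROI-line record is present.
#'
#' @param records list of `count_record`s.
#' @param path output csv.
#' @export
write_count_report <- function(records, path) {
  rows <- lapply(records, function(r)
    data.frame(method = r$method, total = r$total,
               ids = paste(r$counted_ids, collapse = ";")))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  for (r in records) {
    if (identical(r$method, "roi_line") && length(r$crossing_frame)) {
      cp <- sub("\\.csv$", "_crossings.csv", path)
      utils::write.csv(data.frame(id = as.integer(names(r$crossing_frame)),
                                  crossing_frame = as.integer(r$crossing_frame)),
                       cp, row.names = FALSE)
    }
  }
  invisible(path)
}
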