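#' Construct a behavior event series
#'
#' A list of bouts of one behavior as half-open frame intervals
#' `[onset_frame, offset_frame)`, 0-based, sorted and non-overlapping.
#'
#' @param behavior Behavior label.
#' @param onset_frame,offset_frame Integer vectors of equal length.
#' @param fps Frame rate used to convert to seconds.
#' @return Object of class `event_series`; a data frame with columns
#'   `onset_frame`, `offset_frame`, `onset_s`, `offset_s`, `duration_s`
#'   under `$events`.
#' @export
event_series <- function(behavior, onset_frame, offset_frame, fps) {
  stopifnot(length(onset_frame) == length(offset_frame), fps > 0)
  if (length(onset_frame)) {
    o <- order(onset_frame)
    onset_frame <- as.integer(onset_frame[o])
    offset_frame <- as.integer(offset_frame[o])
    if (any(offset_frame <= onset_frame)) {
      stop_ctx("every event needs duration >= 1 frame",
               class = "skeletrack_invalid")
    }
    if (length(onset_frame) > 1L &&
        any(onset_frame[-1L] < offset_frame[-length(offset_frame)])) {
      stop_ctx("events overlap", class = "skeletrack_invalid")
    }
  }
  events <- data.frame(onset_frame = as.integer(onset_frame),
                       offset_frame = as.integer(offset_frame))
  events$onset_s <- events$onset_frame / fps
  events$offset_s <- events$offset_frame / fps
  events$duration_s <- (events$offset_frame - events$onset_frame) / fps
  structure(list(behavior = behavior, events = events, fps = fps),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s: %d events, %.6g s total @ %g fps\n",
              x$behavior, nrow(x$events), sum(x$events$duration_s), x$fps))
  if (nrow(x$events)) print(utils::head(x$events, 10L))
  invisible(x)
}

#' Number of events in a series
#' @param es An [event_series()].
#' @return Integer count.
#' @export
n_events <- function(es) nrow(es$events)

#' Total duration of a series in seconds
#' @param es An [event_series()].
#' @return Seconds.
#' @export
total_duration_s <- function(es) sum(es$events$duration_s)

#' Segment per-frame flags into behavior bouts
#'
#' Converts a boolean per-frame series into events in two passes that mirror
#' the conventional bout rules: first, gaps between consecutive true-runs no
#' longer than `merge_gap_ms` are merged (a recurrence that quickly follows
#' a bout is counted as part of it); second, merged runs shorter than
#' `min_duration_ms` are discarded.  Durations are `n_frames * 1000 / fps`.
#'
#' @param flags Logical vector, one element per frame.
#' @param fps Frame rate (> 0).
#' @param behavior Label for the resulting series.
#' @param min_duration_ms Minimum bout duration kept, milliseconds
#'   (default 150).
#' @param merge_gap_ms Maximum gap bridged between bouts, milliseconds
#'   (default 150).
#' @return An [event_series()] with 0-based half-open frame intervals.
#' @export
#' @examples
#' flags <- rep(FALSE, 50)
#' flags[21:31] <- TRUE; flags[33:41] <- TRUE   # 1-frame gap at 25 fps
#' segment_events(flags, fps = 25)$events        # merged into one bout
segment_events <- function(flags, fps, behavior = "behavior",
                           min_duration_ms = 150, merge_gap_ms = 150) {
  stopifnot(is.logical(flags), fps > 0)
  flags[is.na(flags)] <- FALSE
  if (!length(flags) || !any(flags)) {
    return(event_series(behavior, integer(), integer(), fps))
  }
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values] - 1L        # 0-based onsets
  off <- ends[r$values]              # exclusive offsets
  frame_ms <- 1000 / fps
  # pass 1: merge across short gaps
  if (length(on) > 1L) {
    gap_ms <- (on[-1L] - off[-length(off)]) * frame_ms
    keep_break <- gap_ms > merge_gap_ms
    on <- on[c(TRUE, keep_break)]
    off <- off[c(keep_break, TRUE)]
  }
  # pass 2: drop short bouts
  keep <- (off - on) * frame_ms >= min_duration_ms
  event_series(behavior, on[keep], off[keep], fps)
}

#' Per-frame flags of an event series
#' @param es An [event_series()].
#' @param n_frames Length of the output vector.
#' @return Logical vector: `TRUE` on frames covered by an event.
#' @export
events_to_flags <- function(es, n_frames) {
  flags <- rep(FALSE, n_frames)
  for (i in seq_len(nrow(es$events))) {
    a <- es$events$onset_frame[i] + 1L
    b <- min(es$events$offset_frame[i], n_frames)
    if (a <= b) flags[a:b] <- TRUE
  }
  flags
}

#' Convert an event series to an annotation track
#' @param es An [event_series()].
#' @param session_id,rater_id Identifiers for the track.
#' @return An [annotation_track()].
#' @export
events_to_annotations <- function(es, session_id = "session",
                                  rater_id = "skeletrack") {
  seg <- data.frame(behavior = rep(es$behavior, nrow(es$events)),
                    onset_s = es$events$onset_s,
                    offset_s = es$events$offset_s)
  annotation_track(seg, session_id = session_id, rater_id = rater_id)
}
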