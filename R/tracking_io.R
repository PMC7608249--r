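#' Read a DeepLabCut-format trajectory table
#'
#' Parses the standard DLC CSV layout: a 3-row header (scorer row, bodyparts
#' row, coords row with x / y / likelihood per bodypart) over a frame-index
#' first column, one row per video frame.  The single-animal "individuals"
#' header variant (an extra individuals row below the scorer row) is
#' accepted.  Missing cells become `NA`.
#'
#' @param path Path to the CSV file.
#' @param fps Frame rate of the source video, frames per second.
#' @param session_id Session identifier; defaults to the file name.
#' @param landmark_names Keypoint names that are arena landmarks rather than
#'   animal body points.
#' @return A [tracking_dataset()].
#' @export
read_dlc_tracking <- function(path, fps, session_id = NULL,
                              landmark_names = character()) {
  if (!file.exists(path)) {
    stop_ctx("file not found: ", path, class = "skeletrack_io")
  }
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) < 3L) {
    stop_ctx("not a DLC table (fewer than 3 header rows): ", path,
             class = "skeletrack_format")
  }
  first_col <- raw[[1L]]
  hdr_tags <- c("scorer", "individuals", "bodyparts", "coords")
  n_hdr <- 0L
  while (n_hdr < nrow(raw) && first_col[n_hdr + 1L] %in% hdr_tags) {
    n_hdr <- n_hdr + 1L
  }
  tags <- first_col[seq_len(n_hdr)]
  if (!("bodyparts" %in% tags) || !("coords" %in% tags)) {
    stop_ctx("malformed DLC header: expected 'bodyparts' and 'coords' rows, ",
             "found rows: ", paste(tags, collapse = ", "),
             class = "skeletrack_format")
  }
  bp_row <- as.character(raw[match("bodyparts", tags), -1L])
  co_row <- as.character(raw[match("coords", tags), -1L])
  if (length(bp_row) %% 3L != 0L) {
    stop_ctx("malformed DLC header: column count not a multiple of 3 ",
             "(coords row must be x, y, likelihood per bodypart)",
             class = "skeletrack_format")
  }
  n_bp <- length(bp_row) %/% 3L
  bodyparts <- bp_row[seq(1L, by = 3L, length.out = n_bp)]
  for (i in seq_len(n_bp)) {
    idx <- (i - 1L) * 3L + 1:3
    if (!identical(bp_row[idx], rep(bodyparts[i], 3L))) {
      stop_ctx("malformed bodyparts row: bodypart '", bodyparts[i],
               "' does not span 3 consecutive columns",
               class = "skeletrack_format")
    }
    if (!identical(co_row[idx], c("x", "y", "likelihood"))) {
      stop_ctx("malformed coords row for bodypart '", bodyparts[i],
               "': expected x, y, likelihood; got ",
               paste(co_row[idx], collapse = ", "),
               class = "skeletrack_format")
    }
  }
  body <- raw[-seq_len(n_hdr), , drop = FALSE]
  n_frames <- nrow(body)
  num <- function(v) suppressWarnings(as.numeric(v))
  if (n_frames > 0L) {
    ord <- order(num(body[[1L]]))
    body <- body[ord, , drop = FALSE]
  }
  take <- function(offset) {
    m <- matrix(NA_real_, nrow = n_frames, ncol = n_bp,
                dimnames = list(NULL, bodyparts))
    for (i in seq_len(n_bp)) {
      m[, i] <- num(body[[1L + (i - 1L) * 3L + offset]])
    }
    m
  }
  tracking_dataset(x = take(1L), y = take(2L), likelihood = take(3L),
                   fps = fps,
                   session_id = session_id %||% sub("\\.csv$", "", basename(path)),
                   landmark_names = intersect(landmark_names, bodyparts))
}

#' Write a tracking dataset as a DLC-format CSV
#'
#' Emits the 3-row DLC header and full-precision (17 significant digit)
#' numeric values, so a write / read round trip preserves every coordinate
#' bit-for-bit.
#'
#' @param ds A [tracking_dataset()].
#' @param path Output file path.
#' @param scorer Value for the scorer header row.
#' @return Invisibly, `path`.
#' @export
write_dlc_tracking <- function(ds, path, scorer = "skeletrack") {
  stopifnot(inherits(ds, "tracking_dataset"))
  bodyparts <- colnames(ds$x)
  n_bp <- length(bodyparts)
  hdr1 <- c("scorer", rep(scorer, 3L * n_bp))
  hdr2 <- c("bodyparts", rep(bodyparts, each = 3L))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), n_bp))
  lines <- c(paste(hdr1, collapse = ","),
             paste(hdr2, collapse = ","),
             paste(hdr3, collapse = ","))
  if (ds$n_frames > 0L) {
    cells <- matrix("", nrow = ds$n_frames, ncol = 1L + 3L * n_bp)
    cells[, 1L] <- as.character(seq_len(ds$n_frames) - 1L)
    for (i in seq_len(n_bp)) {
      cells[, 1L + (i - 1L) * 3L + 1L] <- fmt_full(ds$x[, i])
      cells[, 1L + (i - 1L) * 3L + 2L] <- fmt_full(ds$y[, i])
      cells[, 1L + (i - 1L) * 3L + 3L] <- fmt_full(ds$likelihood[, i])
    }
    lines <- c(lines, apply(cells, 1L, paste, collapse = ","))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Construct a temporal behavior annotation track
#'
#' Holds manually scored behavior segments (e.g. exported from the VIA video
#' annotator and reduced to a minimal CSV): one row per bout with a behavior
#' label and onset / offset in seconds.
#'
#' @param segments Data frame with columns `behavior`, `onset_s`, `offset_s`.
#' @param session_id Session identifier.
#' @param rater_id Annotator identifier.
#' @return An object of class `annotation_track`; segments sorted by onset.
#' @export
annotation_track <- function(segments, session_id = "session",
                             rater_id = "rater") {
  segments <- as.data.frame(segments)
  need <- c("behavior", "onset_s", "offset_s")
  if (!all(need %in% names(segments))) {
    stop_ctx("segments need columns behavior, onset_s, offset_s",
             class = "skeletrack_invalid")
  }
  segments <- segments[need]
  if (nrow(segments)) {
    bad <- which(!(segments$onset_s < segments$offset_s))
    if (length(bad)) {
      stop_ctx("segment ", bad[[1L]], ": offset_s (", segments$offset_s[bad[1L]],
               ") must exceed onset_s (", segments$onset_s[bad[1L]], ")",
               class = "skeletrack_invalid")
    }
    segments <- segments[order(segments$onset_s, segments$offset_s), ,
                         drop = FALSE]
    rownames(segments) <- NULL
    for (b in unique(segments$behavior)) {
      s <- segments[segments$behavior == b, , drop = FALSE]
      if (nrow(s) > 1L &&
          any(s$onset_s[-1L] < s$offset_s[-nrow(s)])) {
        stop_ctx("overlapping segments for behavior '", b, "'",
                 class = "skeletrack_invalid")
      }
    }
  }
  structure(list(session_id = session_id, rater_id = rater_id,
                 segments = segments),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %s (rater %s): %d segments\n",
              x$session_id, x$rater_id, nrow(x$segments)))
  if (nrow(x$segments)) print(utils::head(x$segments, 10L))
  invisible(x)
}

#' Read behavior annotations from the minimal CSV dialect
#'
#' The accepted dialect is a header row `behavior,onset_s,offset_s` followed
#' by one row per scored bout.  Rows with `offset_s <= onset_s` raise a
#' validation error naming the row.
#'
#' @param path CSV path.
#' @param session_id,rater_id Identifiers stored on the track.
#' @return An [annotation_track()], segments sorted by onset, labels
#'   preserved verbatim.
#' @export
read_annotations <- function(path, session_id = NULL, rater_id = "rater") {
  if (!file.exists(path)) {
    stop_ctx("file not found: ", path, class = "skeletrack_io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df <- data.frame(behavior = character(), onset_s = numeric(),
                     offset_s = numeric())
  }
  need <- c("behavior", "onset_s", "offset_s")
  if (!all(need %in% names(df))) {
    stop_ctx("annotation file must have columns behavior, onset_s, offset_s: ",
             path, class = "skeletrack_format")
  }
  if (nrow(df)) {
    bad <- which(!(df$onset_s < df$offset_s))
    if (length(bad)) {
      stop_ctx("row ", bad[[1L]], " of ", basename(path),
               ": offset_s must exceed onset_s", class = "skeletrack_invalid")
    }
  }
  annotation_track(df, session_id = session_id %||%
                     sub("\\.csv$", "", basename(path)),
                   rater_id = rater_id)
}

#' Write behavior annotations to the minimal CSV dialect
#' @param ann An [annotation_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_track"))
  seg <- ann$segments
  lines <- c("behavior,onset_s,offset_s",
             if (nrow(seg)) paste(seg$behavior, fmt_full(seg$onset_s),
                                  fmt_full(seg$offset_s), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Rasterize annotation segments to per-frame labels
#'
#' Frame `f` (0-based) spans the time interval `[f/fps, (f+1)/fps)`; it
#' receives the label of the segment containing its midpoint `(f+0.5)/fps`,
#' or `default_label` if no segment covers the midpoint.
#'
#' @param ann An [annotation_track()].
#' @param fps Frame rate (> 0).
#' @param n_frames Number of frames to label.
#' @param default_label Label for frames outside every segment.
#' @return Character vector of length `n_frames`.
#' @export
annotations_to_frame_labels <- function(ann, fps, n_frames,
                                        default_label = "none") {
  stopifnot(inherits(ann, "annotation_track"), fps > 0, n_frames >= 0)
  labels <- rep(default_label, n_frames)
  if (n_frames == 0L || nrow(ann$segments) == 0L) return(labels)
  mid <- (seq_len(n_frames) - 0.5) / fps
  seg <- ann$segments
  assigned_by <- rep(NA_integer_, n_frames)
  for (i in seq_len(nrow(seg))) {
    hit <- mid >= seg$onset_s[i] & mid < seg$offset_s[i]
    prev <- which(hit & !is.na(assigned_by))
    prev <- prev[seg$behavior[assigned_by[prev]] != seg$behavior[i]]
    if (length(prev)) {
      stop_ctx("overlapping segments with different labels ('",
               seg$behavior[assigned_by[prev[1L]]], "' vs '",
               seg$behavior[i], "')", class = "skeletrack_invalid")
    }
    labels[hit] <- seg$behavior[i]
    assigned_by[hit] <- i
  }
  labels
}
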