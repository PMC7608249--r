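#' Default body-outline keypoints
#'
#' Order of keypoints forming the simple polygon around the mouse body used
#' for the floating detector's "body area".
#' @return Character vector of 8 keypoint names.
#' @export
body_outline_points <- function() {
  c("nose", "ear_left", "flank_left", "hip_left", "tail_base",
    "hip_right", "flank_right", "ear_right")
}

#' Per-frame body polygon area
#'
#' Shoelace area of the polygon through the listed keypoints, in the order
#' given, per frame.  During immobility this area is nearly constant; while
#' swimming or moving it fluctuates, which is what the floating detector
#' thresholds.
#'
#' @param ds A [tracking_dataset()] (calibrated units recommended).
#' @param area_points Keypoint names in polygon order (>= 3).
#' @return Numeric vector of areas (units^2) per frame.
#' @export
body_area_series <- function(ds, area_points = body_outline_points()) {
  stopifnot(inherits(ds, "tracking_dataset"))
  if (length(area_points) < 3L) {
    stop_ctx("need at least 3 keypoints for a body polygon",
             class = "skeletrack_domain")
  }
  require_keypoints(ds, area_points)
  X <- ds$x[, area_points, drop = FALSE]
  Y <- ds$y[, area_points, drop = FALSE]
  n <- length(area_points)
  nxt <- c(2:n, 1L)
  abs(rowSums(X * Y[, nxt, drop = FALSE] - X[, nxt, drop = FALSE] * Y)) / 2
}

#' Configuration of the floating detector
#'
#' @param area_points Keypoints of the body polygon (see
#'   [body_area_series()]).
#' @param rate_threshold Immobility threshold on the smoothed absolute
#'   relative rate of change of the body area, in units of (fraction of the
#'   session-median body area) per second.  Default 2.0: while floating the
#'   outline is static, so the local rate sits at the tracker-noise floor
#'   (well under 1); paddling strokes drive it severalfold above the
#'   threshold.
#' @param min_duration_ms Minimum bout duration kept (default 150 ms).
#' @param merge_gap_ms Maximum gap merged between bouts (default 150 ms).
#' @param rate_window_frames Number of consecutive area increments pooled
#'   (root mean square) into the per-frame rate estimate (default 4,
#'   i.e. a 5-frame centered window).  Pooling matters at bout edges: a
#'   single increment can be near zero mid-swim by chance, whereas the RMS
#'   of several almost never is, so the detected boundary tracks the true
#'   mobility change within a frame or two.
#' @param smoothing_window_frames Width of the centered running median
#'   applied to the rate series (odd; default 25, about 1 s at 25 fps).
#'   A wider window rejects longer artifacts; because a step change in
#'   mobility flips the window's majority right at the boundary, widening
#'   it does not delay detected bout edges.
#' @return A list of class `floating_config`.
#' @export
floating_config <- function(area_points = body_outline_points(),
                            rate_threshold = 2.0,
                            min_duration_ms = 150,
                            merge_gap_ms = 150,
                            rate_window_frames = 4,
                            smoothing_window_frames = 25) {
  if (rate_threshold <= 0 || min_duration_ms <= 0) {
    stop_ctx("thresholds must be positive", class = "skeletrack_invalid")
  }
  w <- as.integer(smoothing_window_frames)
  if (w < 1L || w %% 2L == 0L) {
    stop_ctx("smoothing_window_frames must be odd and >= 1",
             class = "skeletrack_invalid")
  }
  k <- as.integer(rate_window_frames)
  if (k < 1L) {
    stop_ctx("rate_window_frames must be >= 1", class = "skeletrack_invalid")
  }
  structure(list(area_points = area_points, rate_threshold = rate_threshold,
                 min_duration_ms = min_duration_ms,
                 merge_gap_ms = merge_gap_ms,
                 rate_window_frames = k,
                 smoothing_window_frames = w),
            class = "floating_config")
}

# Centered moving average with edge shrinkage (partial windows at the
# ends), so the output has the same length as the input.
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered running median; at the ends the centered window is truncated to
# the available frames (still >= half a window wide), so edge values remain
# robust summaries rather than near-raw samples.
running_median <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  if (n <= window) {
    return(vapply(seq_len(n), function(i) {
      stats::median(x[max(1L, i - half):min(n, i + half)])
    }, 0))
  }
  out <- stats::runmed(x, window, endrule = "keep")
  for (i in c(seq_len(half), (n - half + 1L):n)) {
    out[i] <- stats::median(x[max(1L, i - half):min(n, i + half)])
  }
  out
}

#' Detect floating (immobility) from body-area dynamics
#'
#' A frame is flagged as floating when the smoothed absolute rate of change
#' of the body polygon area, expressed relative to the session-median area,
#' falls below `rate_threshold` per second.  Flags are segmented into bouts
#' with [segment_events()] (gap merging then minimum duration).
#'
#' @param area Numeric vector of per-frame body areas, e.g. from
#'   [body_area_series()].
#' @param fps Frame rate.
#' @param cfg A [floating_config()].
#' @return An [event_series()] labeled `"floating"`.
#' @export
detect_floating <- function(area, fps, cfg = floating_config()) {
  stopifnot(inherits(cfg, "floating_config"), fps > 0)
  if (length(area) < 2L) {
    stop_ctx("need at least 2 frames", class = "skeletrack_invalid")
  }
  med <- stats::median(area, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) {
    stop_ctx("degenerate tracking: body area is zero or missing",
             class = "skeletrack_degenerate")
  }
  # per-frame rate: RMS of the area increments in a short centered window
  n <- length(area)
  d2 <- diff(area)^2
  k <- min(cfg$rate_window_frames, n - 1L)
  lo <- pmax(seq_len(n) - k %/% 2L, 1L)
  hi <- pmin(lo + k - 1L, n - 1L)
  lo <- pmin(lo, hi)
  cs <- cumsum(c(0, d2))
  rate <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)) * fps / med
  # centered running median: a robust local dispersion estimate that a
  # single-frame artifact (stroke extremum, interpolation kink, bout
  # transition) cannot drag across the threshold
  smooth <- running_median(rate, cfg$smoothing_window_frames)
  flags <- smooth < cfg$rate_threshold
  segment_events(flags, fps, behavior = "floating",
                 min_duration_ms = cfg$min_duration_ms,
                 merge_gap_ms = cfg$merge_gap_ms)
}

#' Configuration of the head-dip detector
#'
#' @param nose,head Keypoint names for the nose and the head reference
#'   point kept on the maze.
#' @param open_zones Names of the open-arm zones in the arena model.
#' @param min_duration_ms,merge_gap_ms Bout segmentation parameters
#'   (defaults 150 ms each).
#' @return A list of class `head_dip_config`.
#' @export
head_dip_config <- function(nose = "nose", head = "head_centre",
                            open_zones = c("open1", "open2"),
                            min_duration_ms = 150, merge_gap_ms = 150) {
  structure(list(nose = nose, head = head, open_zones = open_zones,
                 min_duration_ms = min_duration_ms,
                 merge_gap_ms = merge_gap_ms),
            class = "head_dip_config")
}

#' Detect head dips on the elevated plus maze
#'
#' A frame is flagged when the nose has left the maze surface (it is outside
#' every maze zone: both open arms, both closed arms and the centre) while
#' the head centre is still on an open arm.  Gating on open-arm occupancy
#' excludes nose excursions along closed-arm walls.  Flags are segmented
#' into bouts with [segment_events()].
#'
#' @param ds Calibrated [tracking_dataset()].
#' @param arena An EPM [build_arena()] model (zones `open1`, `open2`,
#'   `closed1`, `closed2`, `centre`).
#' @param cfg A [head_dip_config()].
#' @return An [event_series()] labeled `"head_dip"`.
#' @export
detect_head_dips <- function(ds, arena, cfg = head_dip_config()) {
  stopifnot(inherits(ds, "tracking_dataset"), inherits(arena, "arena_model"))
  require_calibrated(ds)
  require_keypoints(ds, c(cfg$nose, cfg$head))
  miss <- setdiff(cfg$open_zones, names(arena$zones))
  if (length(miss) || !identical(arena$test_type, "EPM")) {
    stop_ctx("arena model lacks EPM zones: ",
             paste(miss, collapse = ", "), class = "skeletrack_invalid")
  }
  nose <- keypoint_xy(ds, cfg$nose)
  head <- keypoint_xy(ds, cfg$head)
  on_maze <- rep(FALSE, ds$n_frames)
  for (z in arena$zones) on_maze <- on_maze | point_in_zone(nose, z)
  head_on_open <- rep(FALSE, ds$n_frames)
  for (nm in cfg$open_zones) {
    head_on_open <- head_on_open | point_in_zone(head, arena$zones[[nm]])
  }
  flags <- (!on_maze) & head_on_open
  segment_events(flags, ds$fps, behavior = "head_dip",
                 min_duration_ms = cfg$min_duration_ms,
                 merge_gap_ms = cfg$merge_gap_ms)
}
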