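#' Per-keypoint speed, acceleration and distance traveled
#'
#' Speed at frame f is the Euclidean step from frame f-1 times the frame
#' rate (`||p[f] - p[f-1]|| * fps`, cm/s; 0 at the first frame);
#' acceleration is the first difference of speed times the frame rate
#' (cm/s^2); cumulative distance is the running sum of step lengths.
#'
#' @param ds A calibrated [tracking_dataset()] (cm units, >= 2 frames).
#' @param keypoints Keypoints to include; defaults to all animal points.
#' @return A `kinematics_track`: list with matrices `speed`, `acceleration`
#'   (frames x keypoints), `cumulative_distance`, vector `distance_cm`
#'   (total per keypoint), and `fps`.
#' @export
compute_kinematics <- function(ds, keypoints = keypoint_names(ds, animal_only = TRUE)) {
  stopifnot(inherits(ds, "tracking_dataset"))
  require_calibrated(ds)
  require_keypoints(ds, keypoints)
  if (ds$n_frames < 2L) {
    stop_ctx("need at least 2 frames for kinematics",
             class = "skeletrack_invalid")
  }
  x <- ds$x[, keypoints, drop = FALSE]
  y <- ds$y[, keypoints, drop = FALSE]
  step <- rbind(0, sqrt(diff(x)^2 + diff(y)^2))
  speed <- step * ds$fps
  accel <- rbind(0, diff(speed)) * ds$fps
  accel[1:2, ] <- 0   # undefined before two speed samples exist
  cumdist <- apply(step, 2L, cumsum)
  structure(list(speed = speed,
                 acceleration = accel,
                 cumulative_distance = cumdist,
                 distance_cm = cumdist[nrow(cumdist), ],
                 fps = ds$fps),
            class = "kinematics_track")
}

#' Time spent in a zone and number of visits
#'
#' Counts frames whose reference keypoint lies in the zone (boundary
#' inclusive) and converts to seconds; a visit is an outside-to-inside
#' transition, with a session that starts inside counting as a visit.
#'
#' @param ds Calibrated [tracking_dataset()].
#' @param zone Polygon or [zone_region()] in the same (cm) coordinates.
#' @param reference_point Keypoint used as the animal's location (default
#'   `"body_centre"`).
#' @return List with `seconds`, `visits`, and the per-frame logical
#'   `in_zone`.
#' @export
time_in_zone <- function(ds, zone, reference_point = "body_centre") {
  stopifnot(inherits(ds, "tracking_dataset"))
  require_calibrated(ds)
  require_keypoints(ds, reference_point)
  inside <- point_in_zone(keypoint_xy(ds, reference_point), zone)
  entries <- sum(inside & !c(FALSE, inside[-length(inside)]))
  list(seconds = sum(inside) / ds$fps,
       visits = entries,
       in_zone = inside)
}

#' Assign each frame to the first matching zone
#'
#' Zones are tested in the given priority order; a point on a shared
#' boundary goes to the earlier zone.  For the EPM the convention is that
#' arm zones precede the centre, so a mouse on an arm-mouth line counts as
#' in the arm.
#'
#' @param ds Calibrated [tracking_dataset()].
#' @param zones Named list of polygons / [zone_region()]s in priority order.
#' @param reference_point Keypoint used as the animal's location.
#' @param outside_label Label for frames in no zone.
#' @return Character vector of zone names, length `n_frames`.
#' @export
assign_zone <- function(ds, zones, reference_point = "body_centre",
                        outside_label = "outside") {
  require_calibrated(ds)
  pts <- keypoint_xy(ds, reference_point)
  out <- rep(outside_label, ds$n_frames)
  undecided <- rep(TRUE, ds$n_frames)
  for (nm in names(zones)) {
    hit <- undecided & point_in_zone(pts, zones[[nm]])
    out[hit] <- nm
    undecided[hit] <- FALSE
    if (!any(undecided)) break
  }
  out
}

#' Spatial occupancy map
#'
#' Square-cell dwell-time histogram of the reference keypoint over the
#' arena bounding box.  Positions outside the box are clamped into the
#' nearest edge cell, so the grid total always equals the session duration.
#'
#' @param ds Calibrated [tracking_dataset()].
#' @param reference_point Keypoint to histogram.
#' @param bin_size Cell side length in cm (> 0).
#' @param bbox Optional bounding box `c(xmin, xmax, ymin, ymax)`; defaults
#'   to the range of the data.
#' @return Numeric matrix of seconds (rows = y bins, cols = x bins) with
#'   attributes `x_breaks`, `y_breaks`.
#' @export
occupancy_map <- function(ds, reference_point = "body_centre", bin_size = 1,
                          bbox = NULL) {
  require_calibrated(ds)
  if (!is.finite(bin_size) || bin_size <= 0) {
    stop_ctx("bin_size must be positive", class = "skeletrack_domain")
  }
  p <- keypoint_xy(ds, reference_point)
  if (is.null(bbox)) {
    bbox <- c(min(p[, 1L]), max(p[, 1L]), min(p[, 2L]), max(p[, 2L]))
  }
  xb <- seq(bbox[1L], bbox[2L] + bin_size, by = bin_size)
  yb <- seq(bbox[3L], bbox[4L] + bin_size, by = bin_size)
  ix <- pmin(pmax(findInterval(p[, 1L], xb, rightmost.closed = TRUE), 1L),
             length(xb) - 1L)
  iy <- pmin(pmax(findInterval(p[, 2L], yb, rightmost.closed = TRUE), 1L),
             length(yb) - 1L)
  grid <- matrix(0, nrow = length(yb) - 1L, ncol = length(xb) - 1L)
  for (f in seq_len(nrow(p))) {
    grid[iy[f], ix[f]] <- grid[iy[f], ix[f]] + 1
  }
  grid <- grid / ds$fps
  attr(grid, "x_breaks") <- xb
  attr(grid, "y_breaks") <- yb
  grid
}

#' Signed head angle from nose, neck and tail base
#'
#' The angle between the body axis (tail base to neck) and the head axis
#' (neck to nose), signed: positive when the nose deviates toward the
#' animal's left.  Coordinates are image coordinates (y down), for which
#' the animal's left appears clockwise on screen; the sign flip for that
#' convention is applied internally so the reported sign is anatomical.
#' Range (-180, 180]; frames with a zero-length axis are `NA`.
#'
#' @param ds A [tracking_dataset()] containing `nose`, `neck`, `tail_base`.
#' @param nose,neck,tail_base Keypoint names to use for the three points.
#' @return Numeric vector of degrees per frame.
#' @export
head_angle <- function(ds, nose = "nose", neck = "neck",
                       tail_base = "tail_base") {
  stopifnot(inherits(ds, "tracking_dataset"))
  require_keypoints(ds, c(nose, neck, tail_base))
  b <- keypoint_xy(ds, neck) - keypoint_xy(ds, tail_base)
  h <- keypoint_xy(ds, nose) - keypoint_xy(ds, neck)
  signed_angle_deg(b, h, image_coords = TRUE)
}

# Signed angle (degrees) from vector a to vector b per row; counterclockwise
# positive in a y-up frame.  With image_coords = TRUE the sign is flipped so
# that "the animal's left" stays positive under y-down image coordinates.
# Zero vectors give NA; exactly collinear gives 0 or 180.
signed_angle_deg <- function(a, b, image_coords = FALSE) {
  cross <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  if (image_coords) cross <- -cross
  dot <- a[, 1L] * b[, 1L] + a[, 2L] * b[, 2L]
  ang <- atan2(cross, dot) * 180 / pi
  zero <- rowSums(a^2) == 0 | rowSums(b^2) == 0
  ang[zero] <- NA_real_
  # atan2 returns (-180, 180]; map -180 (numerically possible) to +180
  ang[!is.na(ang) & ang <= -180] <- 180
  ang
}
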