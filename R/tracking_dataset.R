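#' The default 13-point mouse keypoint schema
#'
#' Ordered names of the body points tracked on the mouse: nose, head centre,
#' both ears, neck, body centre, both flanks, both hips, tail base, tail
#' centre and tail tip.  All skeletal feature definitions in
#' [extract_skeleton_features()] refer to these names.  The schema is a
#' convention, not a constraint: datasets may carry any keypoint names, but
#' the skeleton feature extractor and the synthetic generator require these
#' thirteen to be present.
#'
#' @return Character vector of 13 keypoint names.
#' @export
#' @examples
#' mouse_schema()
mouse_schema <- function() {
  c("nose", "head_centre", "ear_left", "ear_right", "neck",
    "body_centre", "flank_left", "flank_right", "hip_left", "hip_right",
    "tail_base", "tail_centre", "tail_tip")
}

#' Construct a tracking dataset
#'
#' Container for per-frame keypoint trajectories: for every named keypoint a
#' series of x, y (pixels, or centimeters once calibrated) and a tracker
#' likelihood in \[0, 1\].  Coordinates are image coordinates: the origin is
#' the top-left corner of the frame and y increases downward.  This matters
#' for signed angles (see [head_angle()]).
#'
#' @param x,y,likelihood Numeric matrices, `n_frames` rows and one column per
#'   keypoint, with identical column names in identical order.
#' @param fps Frame rate in frames per second (> 0).
#' @param session_id Identifier for the session (defaults to "session").
#' @param landmark_names Subset of the keypoint names that track static
#'   arena features (corners, arm ends, beaker rim) rather than the animal.
#' @param units `"px"` (raw tracker output) or `"cm"` (after [to_cm()]).
#' @param px_per_cm Optional calibration scalar (pixels per centimeter).
#'
#' @return An object of class `tracking_dataset`.
#' @export
tracking_dataset <- function(x, y, likelihood, fps, session_id = "session",
                             landmark_names = character(),
                             units = "px", px_per_cm = NA_real_) {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  if (!identical(dim(x), dim(y)) || !identical(dim(x), dim(likelihood))) {
    stop_ctx("x, y and likelihood must have identical dimensions",
             class = "skeletrack_invalid")
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop_ctx("keypoint matrices need unique column names",
             class = "skeletrack_invalid")
  }
  colnames(y) <- colnames(likelihood) <- colnames(x)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop_ctx("fps must be a single positive number",
             class = "skeletrack_invalid")
  }
  lk <- likelihood[is.finite(likelihood)]
  if (length(lk) && (min(lk) < 0 || max(lk) > 1)) {
    stop_ctx("likelihood values must lie in [0, 1]",
             class = "skeletrack_invalid")
  }
  if (!all(landmark_names %in% colnames(x))) {
    missing <- setdiff(landmark_names, colnames(x))
    stop_ctx("landmark names not present in dataset: ",
             paste(missing, collapse = ", "), class = "skeletrack_invalid")
  }
  units <- match.arg(units, c("px", "cm"))
  structure(list(
    session_id = session_id,
    fps = fps,
    n_frames = nrow(x),
    x = x, y = y, likelihood = likelihood,
    landmark_names = as.character(landmark_names),
    units = units,
    px_per_cm = px_per_cm
  ), class = "tracking_dataset")
}

#' @export
print.tracking_dataset <- function(x, ...) {
  cat(sprintf("<tracking_dataset> %s: %d frames @ %g fps, %d keypoints (%s)\n",
              x$session_id, x$n_frames, x$fps, ncol(x$x), x$units))
  animal <- setdiff(colnames(x$x), x$landmark_names)
  cat("  animal points:", paste(animal, collapse = ", "), "\n")
  if (length(x$landmark_names)) {
    cat("  landmarks:    ", paste(x$landmark_names, collapse = ", "), "\n")
  }
  if (is.finite(x$px_per_cm)) {
    cat(sprintf("  calibration:   %.6g px/cm\n", x$px_per_cm))
  }
  invisible(x)
}

#' Keypoint names of a tracking dataset
#' @param ds A `tracking_dataset`.
#' @param animal_only Drop arena landmark names?
#' @return Character vector.
#' @export
keypoint_names <- function(ds, animal_only = FALSE) {
  nms <- colnames(ds$x)
  if (animal_only) setdiff(nms, ds$landmark_names) else nms
}

#' Extract one keypoint's coordinates
#' @param ds A `tracking_dataset`.
#' @param name Keypoint name.
#' @return `n_frames` x 2 matrix with columns x, y.
#' @export
keypoint_xy <- function(ds, name) {
  if (!name %in% colnames(ds$x)) {
    stop_ctx("unknown keypoint: ", name, class = "skeletrack_unknown_keypoint")
  }
  cbind(x = ds$x[, name], y = ds$y[, name])
}

# Internal: require that named keypoints exist, error naming the first
# missing one.
require_keypoints <- function(ds, names) {
  miss <- setdiff(names, colnames(ds$x))
  if (length(miss)) {
    stop_ctx("missing keypoint: ", miss[[1L]],
             class = "skeletrack_unknown_keypoint")
  }
  invisible(TRUE)
}

require_calibrated <- function(ds) {
  if (!identical(ds$units, "cm")) {
    stop_ctx("dataset must be calibrated to cm first (see to_cm())",
             class = "skeletrack_uncalibrated")
  }
  invisible(TRUE)
}
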