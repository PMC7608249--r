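#' Names of the 22 skeletal features
#'
#' The fixed, versioned feature schema of [extract_skeleton_features()]:
#' 11 segment lengths (cm), 6 signed joint angles (degrees), 3 polygon
#' areas (cm^2) and 2 dimensionless shape ratios, all invariant to where
#' the animal is and which way it faces.
#'
#' @return Character vector of 22 feature names.
#' @export
skeleton_feature_names <- function() {
  c(# segment lengths
    "len_nose_headcentre", "len_headcentre_neck", "len_neck_bodycentre",
    "len_bodycentre_tailbase", "len_tailbase_tailcentre",
    "len_tailcentre_tailtip", "len_ear_ear", "len_flank_flank",
    "len_hip_hip", "len_nose_tailbase", "len_neck_tailbase",
    # signed joint angles
    "ang_head_deflection", "ang_body_bend", "ang_tail_bend",
    "ang_ear_axis", "ang_hip_axis", "ang_head_axis",
    # polygon areas
    "area_head", "area_trunk", "area_body",
    # shape ratios
    "ratio_width_length", "ratio_head_trunk")
}

# Feature schema version; bumped whenever the 22-name list or a definition
# changes, and stored inside trained classifier bundles.
SKELETON_SCHEMA_VERSION <- "1.0"

#' Position- and orientation-invariant skeletal features
#'
#' Reduces each frame of a 13-keypoint mouse pose to 22 values that do not
#' depend on where the animal is in the arena or which way it faces:
#' inter-keypoint segment lengths, signed joint angles (bend of head, body
#' and tail, and the orientation of the ear/hip axes relative to the body
#' axis) and shoelace areas of the head, trunk and whole-body polygons,
#' plus two shape ratios (body width over nose-to-tail length, head length
#' over trunk length).  Under a reflection of the coordinates, lengths,
#' areas and ratios are unchanged while signed angles negate.
#'
#' Degenerate frames (coincident keypoints) give zero lengths and areas,
#' and angles of zero by convention; ratios with a zero denominator are 0.
#'
#' @param ds A calibrated [tracking_dataset()] containing the 13 points of
#'   [mouse_schema()].
#' @return A `skeleton_feature_track`: list with `features` (frames x 22
#'   matrix, columns [skeleton_feature_names()]), `mode = "skeleton"`,
#'   `schema_version` and `fps`.
#' @export
extract_skeleton_features <- function(ds) {
  stopifnot(inherits(ds, "tracking_dataset"))
  require_keypoints(ds, mouse_schema())
  P <- function(nm) cbind(ds$x[, nm], ds$y[, nm])
  nose <- P("nose"); headc <- P("head_centre")
  earl <- P("ear_left"); earr <- P("ear_right"); neck <- P("neck")
  bodyc <- P("body_centre"); flkl <- P("flank_left"); flkr <- P("flank_right")
  hipl <- P("hip_left"); hipr <- P("hip_right")
  tailb <- P("tail_base"); tailc <- P("tail_centre"); tailt <- P("tail_tip")

  len <- function(a, b) sqrt(rowSums((a - b)^2))
  ang <- function(a, b) {  # signed angle with 0 convention for zero vectors
    v <- signed_angle_deg(a, b, image_coords = TRUE)
    v[is.na(v)] <- 0
    v
  }
  area3 <- function(...) {
    pts <- list(...)
    n <- length(pts)
    s <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      s <- s + pts[[i]][, 1L] * pts[[j]][, 2L] -
        pts[[j]][, 1L] * pts[[i]][, 2L]
    }
    abs(s) / 2
  }
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, 0)

  l_nose_tailb <- len(nose, tailb)
  l_neck_tailb <- len(neck, tailb)
  l_nose_neck <- len(nose, neck)

  feats <- cbind(
    len(nose, headc), len(headc, neck), len(neck, bodyc),
    len(bodyc, tailb), len(tailb, tailc), len(tailc, tailt),
    len(earl, earr), len(flkl, flkr), len(hipl, hipr),
    l_nose_tailb, l_neck_tailb,
    ang(neck - tailb, nose - neck),        # head deflection
    ang(bodyc - tailb, neck - bodyc),      # body bend
    ang(tailc - tailb, tailt - tailc),     # tail bend
    ang(earl - earr, neck - tailb),        # ear axis vs body axis
    ang(hipl - hipr, neck - tailb),        # hip axis vs body axis
    ang(neck - bodyc, nose - headc),       # head axis vs trunk axis
    area3(nose, earl, neck, earr),         # head polygon
    area3(neck, flkl, hipl, tailb, hipr, flkr),  # trunk polygon
    area3(nose, earl, flkl, hipl, tailb, hipr, flkr, earr),  # whole body
    safe_ratio(len(flkl, flkr), l_nose_tailb),
    safe_ratio(l_nose_neck, l_neck_tailb)
  )
  colnames(feats) <- skeleton_feature_names()
  structure(list(features = feats, mode = "skeleton",
                 feature_names = skeleton_feature_names(),
                 schema_version = SKELETON_SCHEMA_VERSION, fps = ds$fps),
            class = "skeleton_feature_track")
}

#' Per-keypoint acceleration-magnitude features
#'
#' One value per mouse keypoint and frame: the magnitude of the point's
#' acceleration (cm/s^2), from [compute_kinematics()].  This 13-dimensional
#' representation captures the motion energy of the body and is the input
#' used for immobility classification, where the pose itself is
#' uninformative but its dynamics are.
#'
#' @param ds Calibrated [tracking_dataset()] (>= 3 frames).
#' @return A `skeleton_feature_track` with `mode = "acceleration"` and a
#'   frames x 13 feature matrix.
#' @export
extract_acceleration_features <- function(ds) {
  stopifnot(inherits(ds, "tracking_dataset"))
  require_keypoints(ds, mouse_schema())
  if (ds$n_frames < 3L) {
    stop_ctx("need at least 3 frames for accelerations",
             class = "skeletrack_invalid")
  }
  kin <- compute_kinematics(ds, keypoints = mouse_schema())
  feats <- abs(kin$acceleration)
  colnames(feats) <- paste0("acc_", mouse_schema())
  structure(list(features = feats, mode = "acceleration",
                 feature_names = colnames(feats),
                 schema_version = SKELETON_SCHEMA_VERSION, fps = ds$fps),
            class = "skeleton_feature_track")
}

#' Windowed samples for frame classification
#'
#' Builds one training/prediction sample per frame: the feature vectors of
#' a centered window of `window_frames` frames, concatenated (earliest
#' frame first).  Windows extending past the session edges replicate the
#' terminal frame.  The sample inherits the label of its center frame.
#'
#' @param ft A `skeleton_feature_track` (or a plain feature matrix).
#' @param labels Optional per-frame label vector (length = frames).
#' @param window_frames Odd window length (default 15; about 0.6 s at
#'   25 fps).
#' @return List with `x` (frames x (features * window) matrix) and `y`
#'   (labels or `NULL`).
#' @export
make_windows <- function(ft, labels = NULL, window_frames = 15L) {
  feats <- if (inherits(ft, "skeleton_feature_track")) ft$features else as.matrix(ft)
  w <- as.integer(window_frames)
  if (w < 1L || w %% 2L == 0L) {
    stop_ctx("window_frames must be odd", class = "skeletrack_invalid")
  }
  n <- nrow(feats)
  if (w > 2L * n) {
    stop_ctx("window (", w, ") longer than twice the track (", n, " frames)",
             class = "skeletrack_invalid")
  }
  if (!is.null(labels) && length(labels) != n) {
    stop_ctx("labels length must equal the number of frames",
             class = "skeletrack_invalid")
  }
  half <- (w - 1L) %/% 2L
  offs <- (-half):half
  cols <- vector("list", w)
  for (k in seq_len(w)) {
    idx <- pmin(pmax(seq_len(n) + offs[k], 1L), n)
    cols[[k]] <- feats[idx, , drop = FALSE]
  }
  x <- do.call(cbind, cols)
  colnames(x) <- paste0(rep(colnames(feats), w), "_t",
                        rep(offs, each = ncol(feats)))
  list(x = x, y = labels)
}
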