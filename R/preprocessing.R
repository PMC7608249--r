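#' Cleaning configuration for likelihood gating and interpolation
#'
#' @param likelihood_cutoff Samples with tracker likelihood below this value
#'   are discarded and re-estimated by interpolation.  Default 0.95, the
#'   conventional DeepLabCut confidence gate.
#' @param max_gap_frames Longest gap (consecutive discarded frames) that is
#'   interpolated without a warning; `Inf` (default) interpolates any gap.
#'   Gaps longer than this are still filled, but a diagnostic warning is
#'   emitted, since long interpolated stretches are straight lines, not
#'   behavior.
#' @param edge_policy How leading/trailing invalid runs are filled; only
#'   `"hold_nearest"` (repeat the nearest valid sample) is implemented.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(likelihood_cutoff = 0.95,
                            max_gap_frames = Inf,
                            edge_policy = "hold_nearest") {
  if (likelihood_cutoff < 0 || likelihood_cutoff > 1) {
    stop_ctx("likelihood_cutoff must lie in [0, 1]",
             class = "skeletrack_invalid")
  }
  edge_policy <- match.arg(edge_policy, "hold_nearest")
  structure(list(likelihood_cutoff = likelihood_cutoff,
                 max_gap_frames = max_gap_frames,
                 edge_policy = edge_policy),
            class = "cleaning_config")
}

#' Gate low-confidence samples and interpolate the gaps
#'
#' For every keypoint, samples whose likelihood falls below the cutoff (or
#' whose coordinates are missing) are replaced by linear interpolation in
#' time between the nearest valid neighbors, per axis.  Leading and trailing
#' invalid runs are filled by holding the nearest valid value.  The returned
#' dataset has no missing coordinates; the fraction of imputed frames per
#' keypoint is attached as the `"fraction_imputed"` attribute.
#'
#' The operation is idempotent: interpolated values are consistent with
#' re-interpolation between the same anchors, so applying it twice changes
#' nothing.
#'
#' @param ds A [tracking_dataset()].
#' @param cfg A [cleaning_config()].
#' @return A cleaned `tracking_dataset`.
#' @export
filter_and_interpolate <- function(ds, cfg = cleaning_config()) {
  stopifnot(inherits(ds, "tracking_dataset"), inherits(cfg, "cleaning_config"))
  out <- ds
  nms <- colnames(ds$x)
  frac <- stats::setNames(numeric(length(nms)), nms)
  for (nm in nms) {
    lk <- ds$likelihood[, nm]
    invalid <- (!is.finite(lk)) | lk < cfg$likelihood_cutoff |
      !is.finite(ds$x[, nm]) | !is.finite(ds$y[, nm])
    if (all(invalid)) {
      stop_ctx("keypoint '", nm, "' has no valid samples after gating",
               class = "skeletrack_degenerate")
    }
    frac[nm] <- mean(invalid)
    if (!any(invalid)) next
    if (is.finite(cfg$max_gap_frames)) {
      r <- rle(invalid)
      if (any(r$values & r$lengths > cfg$max_gap_frames)) {
        warning(sprintf("keypoint '%s': interpolated gap of %d frames exceeds max_gap_frames = %g",
                        nm, max(r$lengths[r$values]), cfg$max_gap_frames))
      }
    }
    for (axis in c("x", "y")) {
      v <- out[[axis]][, nm]
      v[invalid] <- NA_real_
      # linear interior interpolation; rule = 2 holds the nearest valid
      # value across leading/trailing gaps
      out[[axis]][, nm] <- zoo::na.approx(v, na.rm = FALSE, rule = 2)
    }
  }
  attr(out, "fraction_imputed") <- frac
  out
}

#' Pixel-to-centimeter calibration from arena areas
#'
#' The conversion ratio is obtained by comparing the area of the arena
#' polygon in silico (px^2) with the measured physical arena area (cm^2):
#' `px_per_cm = sqrt(area_px / area_cm)`.
#'
#' @param arena_area_px Arena area in squared pixels (> 0).
#' @param arena_area_cm Measured arena area in squared centimeters (> 0).
#' @return Pixels per centimeter, a positive scalar.
#' @export
#' @examples
#' calibrate_px_per_cm(202500, 45 * 45)  # 10 px per cm
calibrate_px_per_cm <- function(arena_area_px, arena_area_cm) {
  if (!is.finite(arena_area_px) || arena_area_px <= 0 ||
      !is.finite(arena_area_cm) || arena_area_cm <= 0) {
    stop_ctx("areas must be positive", class = "skeletrack_domain")
  }
  sqrt(arena_area_px / arena_area_cm)
}

#' Convert a dataset from pixels to centimeters
#'
#' Divides every coordinate by `px_per_cm` and flips the dataset's units
#' flag; calling it on an already-calibrated dataset is an error, so a
#' pipeline cannot accidentally calibrate twice.
#'
#' @param ds A `tracking_dataset` in pixel units.
#' @param px_per_cm Calibration scalar (> 0), e.g. from
#'   [calibrate_px_per_cm()].
#' @return The dataset in cm units.
#' @export
to_cm <- function(ds, px_per_cm) {
  stopifnot(inherits(ds, "tracking_dataset"))
  if (identical(ds$units, "cm")) {
    stop_ctx("dataset is already calibrated to cm",
             class = "skeletrack_already_calibrated")
  }
  if (!is.finite(px_per_cm) || px_per_cm <= 0) {
    stop_ctx("px_per_cm must be positive", class = "skeletrack_domain")
  }
  ds$x <- ds$x / px_per_cm
  ds$y <- ds$y / px_per_cm
  ds$units <- "cm"
  ds$px_per_cm <- px_per_cm
  ds
}
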