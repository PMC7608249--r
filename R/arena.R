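#' Estimate static landmark positions from tracked frames
#'
#' Arena landmarks (corners, arm ends, rim points) are physically static, so
#' their per-frame tracked positions are reduced to a single robust location:
#' the per-axis median over all frames passing the likelihood gate.  The
#' median makes the estimate immune to occasional tracker glitches.
#'
#' @param ds A [tracking_dataset()].
#' @param landmark_names Names to estimate; defaults to the dataset's
#'   landmark set.
#' @param likelihood_cutoff Frames below this likelihood are ignored.
#' @return Named list of length-2 (x, y) vectors, in the dataset's units.
#' @export
estimate_landmarks <- function(ds, landmark_names = ds$landmark_names,
                               likelihood_cutoff = 0.95) {
  stopifnot(inherits(ds, "tracking_dataset"))
  if (!length(landmark_names)) {
    stop_ctx("no landmark names given", class = "skeletrack_invalid")
  }
  require_keypoints(ds, landmark_names)
  out <- list()
  for (nm in landmark_names) {
    lk <- ds$likelihood[, nm]
    ok <- is.finite(ds$x[, nm]) & is.finite(ds$y[, nm]) &
      is.finite(lk) & lk >= likelihood_cutoff
    if (!any(ok)) {
      stop_ctx("landmark '", nm, "' has no valid samples",
               class = "skeletrack_degenerate")
    }
    out[[nm]] <- c(stats::median(ds$x[ok, nm]), stats::median(ds$y[ok, nm]))
  }
  out
}

# Order points counterclockwise (by signed area convention) around their
# mean; used to build a polygon from unordered corner landmarks.
order_around_centroid <- function(pts) {
  pts <- as.matrix(pts)
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 2L] - ctr[2L], pts[, 1L] - ctr[1L])
  pts[order(ang), , drop = FALSE]
}

#' Landmark names required by each arena template
#' @param test_type One of "OFT", "EPM", "FST".
#' @return Character vector of required landmark names (for FST, any >= 3
#'   rim points are accepted; the returned names are the generator's
#'   default 8).
#' @export
arena_template_landmarks <- function(test_type) {
  switch(test_type,
    OFT = paste0("corner_", 1:4),
    EPM = c("open1_end_a", "open1_end_b", "open2_end_a", "open2_end_b",
            "closed1_end_a", "closed1_end_b", "closed2_end_a", "closed2_end_b",
            "centre_a", "centre_b", "centre_c", "centre_d"),
    FST = paste0("rim_", 1:8),
    stop_ctx("no landmark template for test type '", test_type, "'",
             class = "skeletrack_invalid")
  )
}

#' Build an arena model from landmark positions
#'
#' Reconstructs the test arena in silico from estimated landmark points (in
#' pixels), derives the pixel-to-cm calibration by comparing the in-silico
#' polygon area with the measured physical area, and instantiates the
#' analysis zones of the chosen template, in centimeters:
#'
#' * `OFT`: arena polygon from 4 corner landmarks; zones `center` (the
#'   arena scaled to `center_fraction` of its area about the centroid),
#'   `periphery` (arena minus center), `wall_band` (ring within
#'   `wall_band_cm` of the walls, by true edge offset) and `inner` (its
#'   complement).
#' * `EPM`: 12 landmarks (2 end corners per arm, 4 centre-square corners);
#'   zones `open1`, `open2`, `closed1`, `closed2` (quadrilaterals from the
#'   arm end corners and the two nearest centre corners) and `centre`.
#' * `FST`: >= 3 rim landmarks; a least-squares circle fit gives the beaker
#'   outline (represented as a 64-gon); single zone `beaker`.
#' * `custom`: all landmarks ordered around their centroid form the arena;
#'   proportional `center` zone as for the OFT.
#'
#' @param test_type "OFT", "EPM", "FST" or "custom".
#' @param landmarks Named list of (x, y) pixel positions, e.g. from
#'   [estimate_landmarks()].
#' @param measured_dims Named list of physical dimensions in cm:
#'   OFT `width`, `height`; EPM `arm_length`, `arm_width`; FST `diameter`;
#'   custom `area_cm2`.
#' @param zone_spec Optional overrides: `center_fraction` (default 0.5),
#'   `wall_band_cm` (default 12.5).
#' @return An object of class `arena_model` with elements `test_type`,
#'   `arena_polygon` (cm), `zones` (named list of polygons /
#'   [zone_region()]s, cm), `measured_area_cm`, `px_per_cm`.
#' @export
build_arena <- function(test_type, landmarks, measured_dims,
                        zone_spec = list()) {
  test_type <- match.arg(test_type, c("OFT", "EPM", "FST", "custom"))
  centre_fraction <- zone_spec$center_fraction %||% 0.5
  wall_band_cm <- zone_spec$wall_band_cm %||% 12.5
  lm_mat <- do.call(rbind, landmarks)
  if (is.null(lm_mat) || nrow(lm_mat) < 3L) {
    stop_ctx("need at least 3 landmarks", class = "skeletrack_invalid")
  }
  rownames(lm_mat) <- names(landmarks)

  need_names <- function(required) {
    miss <- setdiff(required, names(landmarks))
    if (length(miss)) {
      stop_ctx("missing landmarks for ", test_type, " template: ",
               paste(miss, collapse = ", "), class = "skeletrack_invalid")
    }
  }

  if (test_type %in% c("OFT", "custom")) {
    if (test_type == "OFT") {
      need_names(arena_template_landmarks("OFT"))
      measured_area <- measured_dims$width * measured_dims$height
    } else {
      measured_area <- measured_dims$area_cm2
      if (is.null(measured_area)) {
        stop_ctx("custom arena needs measured_dims$area_cm2",
                 class = "skeletrack_invalid")
      }
    }
    poly_px <- order_around_centroid(lm_mat)
    ppc <- calibrate_px_per_cm(polygon_area(poly_px), measured_area)
    arena <- poly_px / ppc
    centre <- scale_polygon(arena, centre_fraction)
    zones <- list(center = centre,
                  periphery = zone_region(arena, holes = list(centre)))
    if (test_type == "OFT") {
      wb <- wall_band_zones(arena, wall_band_cm)
      zones$wall_band <- wb$wall_zone
      zones$inner <- wb$inner_zone
    }
  } else if (test_type == "EPM") {
    req <- arena_template_landmarks("EPM")
    need_names(req)
    centre_pts <- lm_mat[c("centre_a", "centre_b", "centre_c", "centre_d"), ]
    centre_poly_px <- order_around_centroid(centre_pts)
    arm_ids <- c("open1", "open2", "closed1", "closed2")
    arm_polys_px <- list()
    for (arm in arm_ids) {
      ea <- lm_mat[paste0(arm, "_end_a"), ]
      eb <- lm_mat[paste0(arm, "_end_b"), ]
      mid <- (ea + eb) / 2
      d <- sqrt(rowSums(sweep(centre_pts, 2L, mid, "-")^2))
      near <- centre_pts[order(d)[1:2], ]
      # order the two mouth corners so the quad ea -> eb -> c(eb) -> c(ea)
      # is simple
      if (sum((near[1L, ] - eb)^2) > sum((near[2L, ] - eb)^2)) {
        near <- near[2:1, ]
      }
      arm_polys_px[[arm]] <- rbind(ea, eb, near[1L, ], near[2L, ])
    }
    area_px <- sum(vapply(arm_polys_px, polygon_area, 0)) +
      polygon_area(centre_poly_px)
    aw <- measured_dims$arm_width
    al <- measured_dims$arm_length
    measured_area <- 4 * al * aw + aw^2
    ppc <- calibrate_px_per_cm(area_px, measured_area)
    zones <- lapply(arm_polys_px, function(p) p / ppc)
    zones$centre <- centre_poly_px / ppc
    # whole-maze outline: union is non-convex; keep the zones as the
    # authoritative geometry and the outline as the ordered hull of all
    # landmark points (used only for bounding boxes / plots)
    arena <- order_around_centroid(lm_mat) / ppc
  } else { # FST
    fit <- fit_circle(lm_mat)
    r_cm <- measured_dims$diameter / 2
    ppc <- fit$radius / r_cm
    arena <- circle_polygon(fit$centre / ppc, r_cm)
    zones <- list(beaker = arena)
    measured_area <- pi * r_cm^2
  }

  structure(list(test_type = test_type,
                 arena_polygon = arena,
                 zones = zones,
                 measured_area_cm = measured_area,
                 px_per_cm = ppc,
                 zone_spec = list(center_fraction = centre_fraction,
                                  wall_band_cm = wall_band_cm)),
            class = "arena_model")
}

#' @export
print.arena_model <- function(x, ...) {
  cat(sprintf("<arena_model> %s: %.6g px/cm, measured %.6g cm^2\n",
              x$test_type, x$px_per_cm, x$measured_area_cm))
  for (nm in names(x$zones)) {
    cat(sprintf("  zone %-10s area %.6g cm^2\n", nm, zone_area(x$zones[[nm]])))
  }
  invisible(x)
}
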