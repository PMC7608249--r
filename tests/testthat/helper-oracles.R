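# Independent reference implementations used as oracles.  These are written
# as literal, slow scans so they stay independent of the package's
# vectorized implementations.

# Bout segmentation: explicit scan for runs, explicit merge loop, explicit
# duration filter.
brute_segment_reference <- function(flags, fps, min_duration_ms = 150,
                                    merge_gap_ms = 150) {
  runs <- list()
  start <- NA
  for (i in seq_along(flags)) {
    if (isTRUE(flags[i]) && is.na(start)) start <- i
    if ((!isTRUE(flags[i])) && !is.na(start)) {
      runs[[length(runs) + 1]] <- c(start, i - 1)
      start <- NA
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, length(flags))
  if (!length(runs)) {
    return(data.frame(onset_frame = integer(), offset_frame = integer()))
  }
  # merge gaps <= merge_gap_ms
  merged <- list(runs[[1]])
  if (length(runs) > 1) {
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      gap_frames <- r[1] - last[2] - 1
      if (gap_frames * 1000 / fps <= merge_gap_ms) {
        merged[[length(merged)]] <- c(last[1], r[2])
      } else {
        merged[[length(merged) + 1]] <- r
      }
    }
  }
  keep <- list()
  for (r in merged) {
    if ((r[2] - r[1] + 1) * 1000 / fps >= min_duration_ms) {
      keep[[length(keep) + 1]] <- r
    }
  }
  if (!length(keep)) {
    return(data.frame(onset_frame = integer(), offset_frame = integer()))
  }
  out <- do.call(rbind, keep)
  data.frame(onset_frame = as.integer(out[, 1] - 1),
             offset_frame = as.integer(out[, 2]))
}

# Literal shoelace sum.
shoelace_oracle <- function(poly) {
  n <- nrow(poly)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
  }
  abs(s) / 2
}

# Star-shaped random polygon: guaranteed simple.
random_star_polygon <- function(n_vertices = 8, r_range = c(1, 5),
                                centre = c(0, 0)) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_range[1], r_range[2])
  cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang))
}

# Point-in-polygon by explicit per-point ray casting (boundary treated as
# inside via a separate segment test).
pip_oracle <- function(p, poly) {
  n <- nrow(poly)
  on_edge <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a <- poly[i, ]; b <- poly[j, ]
    cr <- (p[1] - a[1]) * (b[2] - a[2]) - (p[2] - a[2]) * (b[1] - a[1])
    if (abs(cr) < 1e-9 * max(1, sum(abs(c(a, b))))^2 &&
        p[1] >= min(a[1], b[1]) - 1e-12 && p[1] <= max(a[1], b[1]) + 1e-12 &&
        p[2] >= min(a[2], b[2]) - 1e-12 && p[2] <= max(a[2], b[2]) + 1e-12) {
      on_edge <- TRUE
    }
  }
  if (on_edge) return(TRUE)
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a <- poly[i, ]; b <- poly[j, ]
    if ((a[2] > p[2]) != (b[2] > p[2])) {
      xint <- a[1] + (p[2] - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
      if (p[1] < xint) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# Minimal hand-built tracking dataset around explicit coordinate matrices.
make_ds <- function(x, y, likelihood = NULL, fps = 25, units = "px",
                    landmark_names = character()) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(likelihood)) {
    likelihood <- matrix(1, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  tracking_dataset(x, y, likelihood, fps = fps, units = units,
                   landmark_names = landmark_names)
}

# A dataset holding the 13-point template at given per-frame positions and
# headings (cm units), optionally post-transformed.
template_ds <- function(pos, theta = NULL, fps = 25) {
  tpl <- skeletrack:::mouse_template()
  n <- nrow(pos)
  if (is.null(theta)) theta <- rep(0, n)
  X <- matrix(NA_real_, n, 13, dimnames = list(NULL, mouse_schema()))
  Y <- X
  for (f in seq_len(n)) {
    R <- rbind(c(cos(theta[f]), -sin(theta[f])),
               c(sin(theta[f]), cos(theta[f])))
    kp <- tpl %*% t(R)
    X[f, ] <- kp[, 1] + pos[f, 1]
    Y[f, ] <- kp[, 2] + pos[f, 2]
  }
  make_ds(X, Y, fps = fps, units = "cm")
}

# Synthetic OFT video prepared for classifier experiments: features +
# ground-truth frame labels.
make_oft_video <- function(seed, n_supported, n_unsupported,
                           duration_s = 60) {
  n_bouts <- n_supported + n_unsupported
  script <- random_behavior_script(
    c(rep("supported_rear", n_supported),
      rep("unsupported_rear", n_unsupported)),
    duration_s, n_bouts, bout_s = c(0.8, 1.6), seed = seed * 977L)
  sc <- synthetic_scenario("OFT", duration_s = duration_s,
                           behavior_script = script, seed = seed)
  sim <- simulate_session(sc)
  rep <- suppressWarnings(analyze_session(sim$tracking,
                                          default_session_config("OFT")))
  list(features = extract_skeleton_features(rep$dataset),
       labels = annotations_to_frame_labels(sim$annotations, sc$fps,
                                            rep$dataset$n_frames),
       annotations = sim$annotations)
}
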