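## Synthetic DLC-format sessions with scripted ground-truth behavior bouts.
## A rigid-ish 13-keypoint mouse template follows a bounded smooth random
## walk; scripted bouts deform it deterministically.  The generator is the
## package's test bench: every pipeline stage can be exercised against known
## ground truth without any video data.

# Canonical mouse template, cm, body centre at the origin, facing +x.
# Image convention (y down): the animal's left is -y when facing +x.
mouse_template <- function() {
  m <- rbind(
    nose        = c( 4.0,  0.0),
    head_centre = c( 3.0,  0.0),
    ear_left    = c( 2.6, -0.9),
    ear_right   = c( 2.6,  0.9),
    neck        = c( 2.2,  0.0),
    body_centre = c( 0.0,  0.0),
    flank_left  = c( 0.2, -1.4),
    flank_right = c( 0.2,  1.4),
    hip_left    = c(-1.6, -1.0),
    hip_right   = c(-1.6,  1.0),
    tail_base   = c(-2.2,  0.0),
    tail_centre = c(-4.5,  0.0),
    tail_tip    = c(-7.0,  0.0)
  )
  m[mouse_schema(), , drop = FALSE]
}

behaviors_for_test <- function(test_type) {
  switch(test_type,
         OFT = c("supported_rear", "unsupported_rear"),
         EPM = "head_dip",
         FST = "floating")
}

#' Describe a synthetic tracking session
#'
#' @param test_type "OFT", "EPM" or "FST".
#' @param duration_s Session length in seconds (defaults: 600 for OFT/EPM,
#'   360 for FST, the standard test durations).
#' @param fps Frame rate (default 25).
#' @param behavior_script Data frame `behavior`, `onset_s`, `offset_s` of
#'   scripted bouts; only behaviors defined for the test type are allowed
#'   (OFT: supported_rear / unsupported_rear; EPM: head_dip; FST:
#'   floating).  Bouts must not overlap.
#' @param noise_sd_px Gaussian tracker noise added to every emitted
#'   coordinate, pixels (default 0.5, a typical sub-pixel DLC jitter).
#' @param dropout_rate Fraction of samples given likelihood 0.1 and a large
#'   corrupted coordinate jump, emulating tracker failures (default 0.02).
#' @param seed Integer seed; the scenario is fully reproducible from it.
#' @param px_per_cm True pixel scale of the virtual camera (default 10).
#' @param arena_dims Physical dimensions (cm); defaults: OFT 45 x 45, EPM
#'   arms 65.5 x 5.5, FST diameter 20.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(test_type, duration_s = NULL, fps = 25,
                               behavior_script = NULL, noise_sd_px = 0.5,
                               dropout_rate = 0.02, seed = 1L,
                               px_per_cm = 10, arena_dims = NULL) {
  test_type <- match.arg(test_type, c("OFT", "EPM", "FST"))
  duration_s <- duration_s %||% switch(test_type, OFT = 600, EPM = 600,
                                       FST = 360)
  arena_dims <- arena_dims %||% switch(test_type,
    OFT = list(width = 45, height = 45),
    EPM = list(arm_length = 65.5, arm_width = 5.5),
    FST = list(diameter = 20))
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_ctx("dropout_rate must lie in [0, 1)", class = "skeletrack_invalid")
  }
  if (is.null(behavior_script)) {
    behavior_script <- data.frame(behavior = character(),
                                  onset_s = numeric(), offset_s = numeric())
  }
  behavior_script <- as.data.frame(behavior_script)
  if (nrow(behavior_script)) {
    allowed <- behaviors_for_test(test_type)
    bad <- setdiff(unique(behavior_script$behavior), allowed)
    if (length(bad)) {
      stop_ctx("behavior '", bad[[1L]], "' is not defined for ", test_type,
               " (allowed: ", paste(allowed, collapse = ", "), ")",
               class = "skeletrack_invalid")
    }
    o <- order(behavior_script$onset_s)
    behavior_script <- behavior_script[o, , drop = FALSE]
    if (any(behavior_script$offset_s <= behavior_script$onset_s) ||
        any(behavior_script$offset_s > duration_s)) {
      stop_ctx("script segments must have onset < offset <= duration",
               class = "skeletrack_invalid")
    }
    n <- nrow(behavior_script)
    if (n > 1L && any(behavior_script$onset_s[-1L] <
                      behavior_script$offset_s[-n])) {
      stop_ctx("script segments overlap", class = "skeletrack_invalid")
    }
    rownames(behavior_script) <- NULL
  }
  structure(list(test_type = test_type, duration_s = duration_s, fps = fps,
                 behavior_script = behavior_script,
                 noise_sd_px = noise_sd_px, dropout_rate = dropout_rate,
                 seed = as.integer(seed), px_per_cm = px_per_cm,
                 arena_dims = arena_dims),
            class = "synthetic_scenario")
}

#' Draw a random non-overlapping behavior script
#'
#' Convenience generator of scripted bouts for a scenario: `n_bouts` bouts
#' of the given behaviors with durations uniform in `bout_s`, separated by
#' at least `min_gap_s`.
#'
#' @param behaviors Character vector; each bout's behavior is drawn
#'   uniformly from it.
#' @param duration_s Session length the bouts must fit into.
#' @param n_bouts Number of bouts.
#' @param bout_s Length-2 range of bout durations, seconds.
#' @param min_gap_s Minimum spacing between consecutive bouts (default 1).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Data frame `behavior`, `onset_s`, `offset_s` sorted by onset.
#' @export
random_behavior_script <- function(behaviors, duration_s, n_bouts,
                                   bout_s = c(1, 2), min_gap_s = 1,
                                   seed = NULL) {
  draw <- function() {
    lens <- stats::runif(n_bouts, bout_s[1L], bout_s[2L])
    slack <- duration_s - sum(lens) - min_gap_s * (n_bouts + 1L)
    if (slack < 0) {
      stop_ctx("bouts do not fit into the session", class = "skeletrack_invalid")
    }
    gaps <- stats::runif(n_bouts + 1L)
    gaps <- gaps / sum(gaps) * slack + min_gap_s
    onsets <- cumsum(gaps)[seq_len(n_bouts)] +
      c(0, cumsum(lens))[seq_len(n_bouts)]
    data.frame(behavior = sample(behaviors, n_bouts, replace = TRUE),
               onset_s = round(onsets, 3), offset_s = round(onsets + lens, 3))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Smooth bounded 2-D random walk (AR(1) velocity, reflecting box walls).
# Default step scale gives a mean speed of roughly 7 cm/s at 25 fps,
# matching an actively exploring mouse.
bounded_walk <- function(n, lower, upper, v_sd = 0.15, v_rho = 0.85,
                         start = (lower + upper) / 2) {
  pos <- matrix(0, n, 2L)
  p <- start
  v <- c(0, 0)
  for (f in seq_len(n)) {
    v <- v_rho * v + stats::rnorm(2L, sd = v_sd)
    p <- p + v
    for (k in 1:2) {
      if (p[k] < lower[k]) { p[k] <- 2 * lower[k] - p[k]; v[k] <- -v[k] }
      if (p[k] > upper[k]) { p[k] <- 2 * upper[k] - p[k]; v[k] <- -v[k] }
      p[k] <- min(max(p[k], lower[k]), upper[k])
    }
    pos[f, ] <- p
  }
  pos
}

# Smooth a heading series derived from displacement, holding the previous
# heading while the animal is (nearly) stationary.
heading_from_path <- function(pos, alpha = 0.3) {
  n <- nrow(pos)
  th <- numeric(n)
  d <- rbind(c(1, 0), diff(pos))
  cur <- atan2(d[1L, 2L], d[1L, 1L])
  for (f in seq_len(n)) {
    if (sum(d[f, ]^2) > 1e-6) {
      target <- atan2(d[f, 2L], d[f, 1L])
      delta <- atan2(sin(target - cur), cos(target - cur))
      cur <- cur + alpha * delta
    }
    th[f] <- cur
  }
  th
}

# Landmark positions (cm, arena frame) per test type.
synthetic_landmarks <- function(test_type, dims) {
  switch(test_type,
    OFT = {
      w <- dims$width; h <- dims$height
      list(corner_1 = c(0, 0), corner_2 = c(w, 0),
           corner_3 = c(w, h), corner_4 = c(0, h))
    },
    EPM = {
      aw <- dims$arm_width / 2; al <- dims$arm_length
      list(open1_end_a = c(aw + al, -aw), open1_end_b = c(aw + al, aw),
           open2_end_a = c(-aw - al, -aw), open2_end_b = c(-aw - al, aw),
           closed1_end_a = c(-aw, aw + al), closed1_end_b = c(aw, aw + al),
           closed2_end_a = c(-aw, -aw - al), closed2_end_b = c(aw, -aw - al),
           centre_a = c(-aw, -aw), centre_b = c(aw, -aw),
           centre_c = c(aw, aw), centre_d = c(-aw, aw))
    },
    FST = {
      r <- dims$diameter / 2
      th <- seq(0, 2 * pi, length.out = 9L)[-9L]
      stats::setNames(
        lapply(seq_along(th), function(i) c(r * cos(th[i]), r * sin(th[i]))),
        paste0("rim_", seq_along(th)))
    })
}

#' Simulate a tracking session with scripted ground truth
#'
#' Generates the DLC-style per-frame keypoint table of a 13-point mouse
#' moving in the scenario's arena, plus the arena landmark points, the
#' tracker likelihoods and the ground-truth annotation track.  Scripted
#' bouts deform the skeleton deterministically:
#'
#' * `supported_rear` (OFT): the animal pauses within reach of a wall and
#'   its body axis compresses to 65% (forepaws up on the wall shorten the
#'   top-view outline moderately).
#' * `unsupported_rear` (OFT): pause in the interior, body axis compresses
#'   to 45% with the nose tucked over the body centre (a full upright rear
#'   foreshortens the outline strongly).
#' * `floating` (FST): swimming oscillation stops and the pose freezes, so
#'   body-centre speed and the body-area rate of change collapse.
#' * `head_dip` (EPM): the nose displaces laterally 1.5 cm beyond the open
#'   arm's side edge while the head centre stays on the arm.
#'
#' A frame belongs to a bout when its midpoint time lies inside the bout,
#' matching [annotations_to_frame_labels()].  Dropout samples get
#' likelihood 0.1 and a large uniform coordinate jump; all other samples
#' get likelihoods in \[0.95, 1\].  The output is a pure function of the
#' scenario (including its seed).
#'
#' @param sc A [synthetic_scenario()].
#' @return List with `tracking` (a pixel-unit [tracking_dataset()] whose
#'   landmark names are set), `annotations` (an [annotation_track()]) and
#'   `scenario`.
#' @export
simulate_session <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  with_seed(sc$seed, simulate_session_impl(sc))
}

simulate_session_impl <- function(sc) {
  n <- round(sc$duration_s * sc$fps)
  mid_t <- (seq_len(n) - 0.5) / sc$fps
  template <- mouse_template()
  script <- sc$behavior_script
  frame_beh <- rep("none", n)
  for (i in seq_len(nrow(script))) {
    frame_beh[mid_t >= script$onset_s[i] & mid_t < script$offset_s[i]] <-
      script$behavior[i]
  }
  bout_id <- cumsum(c(TRUE, frame_beh[-1L] != frame_beh[-n]))

  dims <- sc$arena_dims
  if (sc$test_type == "OFT") {
    w <- dims$width; h <- dims$height
    pos <- bounded_walk(n, c(4, 4), c(w - 4, h - 4), v_sd = 0.15,
                        start = c(w / 2, h / 2))
    # rears happen at a fixed spot: near a wall (supported) or in the
    # interior (unsupported); the spot is drawn once per bout
    for (b in unique(bout_id[frame_beh != "none"])) {
      fr <- which(bout_id == b)
      beh <- frame_beh[fr[1L]]
      if (beh == "supported_rear") {
        side <- sample.int(4L, 1L)
        along <- stats::runif(1L, 8, w - 8)
        spot <- switch(side, c(along, 5), c(along, h - 5),
                       c(5, along), c(w - 5, along))
      } else {
        spot <- c(stats::runif(1L, 16, w - 16), stats::runif(1L, 16, h - 16))
      }
      pos[fr, ] <- matrix(spot, length(fr), 2L, byrow = TRUE)
    }
    theta <- heading_from_path(pos)
  } else if (sc$test_type == "EPM") {
    aw <- dims$arm_width / 2; al <- dims$arm_length
    # 1-D walk along the open-arm axis (x), small lateral jitter
    # keep the walk short of the arm ends so the nose never overhangs them
    s <- bounded_walk(n, c(-(al + aw) + 9, -0.5), c(al + aw - 9, 0.5),
                      v_sd = 0.2, start = c(0, 0))
    pos <- s
    for (b in unique(bout_id[frame_beh == "head_dip"])) {
      fr <- which(bout_id == b)
      x0 <- pos[fr[1L], 1L]
      if (abs(x0) < aw + 6) x0 <- sign(x0 + 0.1) * (aw + 20)
      pos[fr, 1L] <- x0
      pos[fr, 2L] <- 0
    }
    theta <- heading_from_path(pos)
    # keep the body on the arm: force heading along +-x
    theta <- ifelse(cos(theta) >= 0, 0, pi)
  } else { # FST
    r <- dims$diameter / 2
    pos <- bounded_walk(n, c(-r + 6, -r + 6), c(r - 6, r - 6), v_sd = 0.3,
                        start = c(0, 0))
    for (b in unique(bout_id[frame_beh == "floating"])) {
      fr <- which(bout_id == b)
      pos[fr, 1L] <- pos[fr[1L], 1L]
      pos[fr, 2L] <- pos[fr[1L], 2L]
    }
    theta <- cumsum(stats::rnorm(n, mean = 0.01, sd = 0.03))
    for (b in unique(bout_id[frame_beh == "floating"])) {
      fr <- which(bout_id == b)
      theta[fr] <- theta[fr[1L]]
    }
  }

  # swim-stroke modulation: a rhythmic stroke plus an irregular broadband
  # component (real strokes are not a pure sinusoid, so the body outline's
  # rate of change never lingers at zero mid-swim)
  swim_phase <- stats::runif(1L, 0, 2 * pi)
  swim_ar <- stats::filter(stats::rnorm(n, sd = 0.05), 0.6,
                           method = "recursive")
  swim_lat <- 0.15 * sin(2 * pi * 2.5 * mid_t + swim_phase) + swim_ar
  swim_lon <- 0.05 * sin(2 * pi * 2.5 * mid_t + swim_phase + pi / 3) +
    0.4 * c(swim_ar[-1L], 0)
  nk <- nrow(template)
  X <- matrix(NA_real_, n, nk, dimnames = list(NULL, rownames(template)))
  Y <- X
  for (f in seq_len(n)) {
    tpl <- template
    beh <- frame_beh[f]
    if (beh == "supported_rear") {
      tpl[, 1L] <- tpl[, 1L] * 0.65
    } else if (beh == "unsupported_rear") {
      tpl[, 1L] <- tpl[, 1L] * 0.45
      tpl[c("nose", "head_centre"), 1L] <-
        tpl[c("nose", "head_centre"), 1L] * 0.5
    } else if (sc$test_type == "FST" && beh != "floating") {
      tpl[, 2L] <- tpl[, 2L] * (1 + swim_lat[f])
      tpl[, 1L] <- tpl[, 1L] * (1 + swim_lon[f])
      # paddling: limbs and tail jitter independently every stroke frame
      limbs <- c("flank_left", "flank_right", "hip_left", "hip_right",
                 "tail_centre", "tail_tip")
      tpl[limbs, ] <- tpl[limbs, ] +
        matrix(stats::rnorm(2L * length(limbs), sd = 0.8),
               ncol = 2L)
    }
    ct <- cos(theta[f]); st <- sin(theta[f])
    R <- rbind(c(ct, -st), c(st, ct))
    kp <- tpl %*% t(R)
    kp <- sweep(kp, 2L, pos[f, ], "+")
    if (beh == "head_dip") {
      # nose leaves the arm surface laterally; head centre stays on-arm
      aw <- dims$arm_width / 2
      kp["nose", 1L] <- kp["head_centre", 1L]
      kp["nose", 2L] <- pos[f, 2L] + (aw + 1.5)
    }
    X[f, ] <- kp[, 1L]
    Y[f, ] <- kp[, 2L]
  }

  # place arena frame into the image (cm offset), then to pixels
  offset <- switch(sc$test_type, OFT = c(10, 10), EPM = c(80, 80),
                   FST = c(15, 15))
  lms <- synthetic_landmarks(sc$test_type, dims)
  lm_names <- names(lms)
  for (nm in lm_names) {
    p <- (lms[[nm]] + offset) * sc$px_per_cm
    X <- cbind(X, rep(p[1L], n))
    Y <- cbind(Y, rep(p[2L], n))
    colnames(X)[ncol(X)] <- colnames(Y)[ncol(Y)] <- nm
  }
  X[, mouse_schema()] <- (X[, mouse_schema()] + offset[1L]) * sc$px_per_cm
  Y[, mouse_schema()] <- (Y[, mouse_schema()] + offset[2L]) * sc$px_per_cm

  # tracker noise, likelihoods and dropout
  nc <- ncol(X)
  if (sc$noise_sd_px > 0) {
    X <- X + matrix(stats::rnorm(n * nc, sd = sc$noise_sd_px), n, nc)
    Y <- Y + matrix(stats::rnorm(n * nc, sd = sc$noise_sd_px), n, nc)
  }
  L <- matrix(stats::runif(n * nc, 0.95, 1), n, nc,
              dimnames = list(NULL, colnames(X)))
  if (sc$dropout_rate > 0) {
    drop <- matrix(stats::runif(n * nc) < sc$dropout_rate, n, nc)
    L[drop] <- 0.1
    X[drop] <- X[drop] + stats::runif(sum(drop), -200, 200)
    Y[drop] <- Y[drop] + stats::runif(sum(drop), -200, 200)
  }

  ds <- tracking_dataset(X, Y, L, fps = sc$fps,
                         session_id = sprintf("synthetic_%s_seed%d",
                                              sc$test_type, sc$seed),
                         landmark_names = lm_names)
  ann <- annotation_track(script, session_id = ds$session_id,
                          rater_id = "ground_truth")
  list(tracking = ds, annotations = ann, scenario = sc)
}

#' Write a standard fixture suite of synthetic sessions
#'
#' Simulates a small set of sessions (3 OFT, 2 EPM, 2 FST) with scripted
#' bouts and writes, for each, the DLC tracking CSV, the ground-truth
#' annotation CSV and a YAML analysis config, plus a `manifest.csv`.
#' Regenerating with the same seed reproduces the files byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed; session i uses `seed + i`.
#' @param duration_s Named durations per test (defaults OFT/EPM 600 s,
#'   FST 360 s).
#' @return Invisibly, a data frame manifest of the written files.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L,
                               duration_s = c(OFT = 600, EPM = 600,
                                              FST = 360)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plan <- data.frame(
    test_type = c("OFT", "OFT", "OFT", "EPM", "EPM", "FST", "FST"),
    id = c("oft_01", "oft_02", "oft_03", "epm_01", "epm_02",
           "fst_01", "fst_02"),
    n_bouts = c(8, 10, 6, 6, 8, 5, 7))
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    tt <- plan$test_type[i]
    dur <- unname(duration_s[tt])
    s <- seed + i
    script <- random_behavior_script(behaviors_for_test(tt), dur,
                                     plan$n_bouts[i], bout_s = c(1, 2.5),
                                     seed = s * 1000L)
    sc <- synthetic_scenario(tt, duration_s = dur, seed = s,
                             behavior_script = script)
    sim <- simulate_session(sc)
    track_path <- file.path(out_dir, paste0(plan$id[i], "_tracking.csv"))
    ann_path <- file.path(out_dir, paste0(plan$id[i], "_annotations.csv"))
    cfg_path <- file.path(out_dir, paste0(plan$id[i], "_config.yaml"))
    write_dlc_tracking(sim$tracking, track_path)
    write_annotations(sim$annotations, ann_path)
    writeLines(yaml::as.yaml(default_session_config(tt, fps = sc$fps)),
               cfg_path)
    rows[[i]] <- data.frame(id = plan$id[i], test_type = tt,
                            tracking = basename(track_path),
                            annotations = basename(ann_path),
                            config = basename(cfg_path), seed = s)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
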