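#' Default analysis configuration for a test type
#'
#' The configuration is a plain named list (serializable to YAML) with the
#' arena template, physical dimensions, cleaning and behavior-detector
#' settings.  `analyze_session()` accepts a YAML file with the same
#' structure; unspecified fields fall back to these defaults.
#'
#' @param test_type "OFT", "EPM" or "FST".
#' @param fps Frame rate of the sessions.
#' @return Named list.
#' @export
default_session_config <- function(test_type, fps = 25) {
  test_type <- match.arg(test_type, c("OFT", "EPM", "FST"))
  list(
    test_type = test_type,
    fps = fps,
    landmarks = arena_template_landmarks(test_type),
    measured_dims = switch(test_type,
      OFT = list(width = 45, height = 45),
      EPM = list(arm_length = 65.5, arm_width = 5.5),
      FST = list(diameter = 20)),
    zone_spec = list(center_fraction = 0.5, wall_band_cm = 12.5),
    cleaning = list(likelihood_cutoff = 0.95, max_gap_frames = Inf),
    reference_point = "body_centre",
    floating = list(rate_threshold = 2.0, min_duration_ms = 150,
                    merge_gap_ms = 150, smoothing_window_frames = 25),
    head_dip = list(min_duration_ms = 150, merge_gap_ms = 150),
    classifier_bundle = NULL
  )
}

read_session_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$test_type)) {
    stop_ctx("config must name a test_type", class = "skeletrack_invalid")
  }
  base <- default_session_config(config$test_type, config$fps %||% 25)
  out <- utils::modifyList(base, config)
  out
}

stage <- function(name, session_id, expr) {
  tryCatch(expr, error = function(e) {
    stop_ctx("[", session_id, " / ", name, "] ", conditionMessage(e),
             class = "skeletrack_stage")
  })
}

#' Analyze one tracking session end to end
#'
#' Runs the full per-session pipeline: read the DLC table, gate and
#' interpolate low-confidence samples, estimate the arena landmarks,
#' build the arena model and pixel-to-cm calibration, compute kinematics
#' and zone occupancy, run the rule-based behavior detectors of the test
#' type (floating for FST, head dips for EPM) and, when a classifier
#' bundle is configured, the supervised rear classifier (OFT).  Any stage
#' failure is reported with the stage name and session id.
#'
#' @param tracking Path to a DLC CSV, or a [tracking_dataset()].
#' @param config Path to a YAML config, or a config list (see
#'   [default_session_config()]).
#' @return A `session_report`: list with `measures` (named numerics),
#'   `events` (list of [event_series()]), `arena`, `dataset` (cleaned,
#'   calibrated) and `config`.
#' @export
analyze_session <- function(tracking, config) {
  cfg <- read_session_config(if (is.character(config)) config else config)
  if (is.character(tracking)) {
    ds <- stage("read", basename(tracking),
                read_dlc_tracking(tracking, fps = cfg$fps,
                                  landmark_names = cfg$landmarks))
  } else {
    ds <- tracking
    if (!all(cfg$landmarks %in% colnames(ds$x))) {
      missing <- setdiff(cfg$landmarks, colnames(ds$x))
      stop_ctx("[", ds$session_id, " / read] missing arena landmark: ",
               paste(missing, collapse = ", "), class = "skeletrack_stage")
    }
    ds$landmark_names <- cfg$landmarks
  }
  sid <- ds$session_id
  clean_cfg <- cleaning_config(cfg$cleaning$likelihood_cutoff %||% 0.95,
                               cfg$cleaning$max_gap_frames %||% Inf)
  ds <- stage("clean", sid, filter_and_interpolate(ds, clean_cfg))
  frac_imp <- attr(ds, "fraction_imputed")
  lms <- stage("landmarks", sid, estimate_landmarks(ds, cfg$landmarks))
  arena <- stage("arena", sid,
                 build_arena(cfg$test_type, lms, cfg$measured_dims,
                             cfg$zone_spec))
  ds <- stage("calibrate", sid, to_cm(ds, arena$px_per_cm))
  ref <- cfg$reference_point
  kin <- stage("kinematics", sid, compute_kinematics(ds))

  measures <- list(
    session_id = sid,
    test_type = cfg$test_type,
    duration_s = ds$n_frames / ds$fps,
    distance_cm = unname(kin$distance_cm[ref]),
    mean_speed_cm_s = mean(kin$speed[-1L, ref]),
    px_per_cm = arena$px_per_cm,
    fraction_imputed = max(frac_imp)
  )
  for (nm in names(arena$zones)) {
    tz <- stage(paste0("zone_", nm), sid,
                time_in_zone(ds, arena$zones[[nm]], ref))
    measures[[paste0("time_in_", nm, "_s")]] <- tz$seconds
    measures[[paste0("visits_", nm)]] <- tz$visits
  }
  if (cfg$test_type == "EPM") {
    measures$time_in_open_s <-
      measures$time_in_open1_s + measures$time_in_open2_s
    measures$time_in_closed_s <-
      measures$time_in_closed1_s + measures$time_in_closed2_s
  }

  events <- list()
  if (cfg$test_type == "FST") {
    fc <- do.call(floating_config, cfg$floating[intersect(
      names(cfg$floating),
      names(formals(floating_config)))])
    area <- stage("floating", sid, body_area_series(ds, fc$area_points))
    es <- stage("floating", sid, detect_floating(area, ds$fps, fc))
    events$floating <- es
    measures$floating_count <- n_events(es)
    measures$floating_total_s <- total_duration_s(es)
  } else if (cfg$test_type == "EPM") {
    hc <- do.call(head_dip_config, cfg$head_dip[intersect(
      names(cfg$head_dip), names(formals(head_dip_config)))])
    es <- stage("head_dip", sid, detect_head_dips(ds, arena, hc))
    events$head_dip <- es
    measures$head_dip_count <- n_events(es)
    measures$head_dip_total_s <- total_duration_s(es)
  } else if (!is.null(cfg$classifier_bundle)) {
    model <- stage("classifier", sid, load_classifier(cfg$classifier_bundle))
    ft <- stage("classifier", sid, extract_skeleton_features(ds))
    pred <- stage("classifier", sid, predict(model, ft))
    for (b in setdiff(model$labels, "none")) {
      es <- labels_to_events(pred, b, ds$fps)
      events[[b]] <- es
      measures[[paste0(b, "_count")]] <- n_events(es)
      measures[[paste0(b, "_total_s")]] <- total_duration_s(es)
    }
  }

  structure(list(measures = measures, events = events, arena = arena,
                 dataset = ds, config = cfg),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  m <- x$measures
  cat(sprintf("<session_report> %s (%s)\n", m$session_id, m$test_type))
  for (nm in setdiff(names(m), c("session_id", "test_type"))) {
    cat(sprintf("  %-24s %s\n", nm, fmt_report(m[[nm]])))
  }
  invisible(x)
}

#' Analyze a batch of sessions and summarize
#'
#' Runs [analyze_session()] over a manifest of tracking files; failures of
#' individual sessions are collected and reported while the successful
#' rows are still emitted.  The summary holds mean, standard deviation and
#' coefficient of variation per numeric measure.
#'
#' @param tracking_paths Character vector of DLC CSV paths (or a list of
#'   [tracking_dataset()]s).
#' @param config Shared config (path or list).
#' @return A `batch_report`: list with `table` (one row per session),
#'   `summary` (per-measure mean / sd / cv_percent), `errors` (named list
#'   of failure messages) and `n_failed`.
#' @export
analyze_batch <- function(tracking_paths, config) {
  reports <- list(); errors <- list()
  for (i in seq_along(tracking_paths)) {
    tr <- if (is.list(tracking_paths)) tracking_paths[[i]] else tracking_paths[i]
    id <- if (inherits(tr, "tracking_dataset")) tr$session_id else basename(tr)
    res <- tryCatch(analyze_session(tr, config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
    } else {
      reports[[length(reports) + 1L]] <- res
    }
  }
  rows <- lapply(reports, function(r) as.data.frame(r$measures))
  table <- if (length(rows)) do.call(rbind, rows) else data.frame()
  summary <- NULL
  if (nrow(table) >= 2L) {
    num <- names(table)[vapply(table, is.numeric, TRUE)]
    summary <- do.call(rbind, lapply(num, function(nm) {
      v <- table[[nm]]
      data.frame(measure = nm, mean = mean(v), sd = stats::sd(v),
                 cv_percent = if (mean(v) != 0)
                   coefficient_of_variation(v) else NA_real_)
    }))
  }
  structure(list(table = table, summary = summary, errors = errors,
                 n_failed = length(errors)),
            class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("<batch_report> %d sessions analyzed, %d failed\n",
              nrow(x$table), x$n_failed))
  if (!is.null(x$summary)) print(x$summary, digits = 6)
  for (nm in names(x$errors)) cat("  FAILED ", nm, ": ", x$errors[[nm]], "\n")
  invisible(x)
}

#' Write a report table with fixed formatting
#'
#' Numbers are written with 6 significant digits so that re-running the
#' same analysis produces byte-identical files.
#'
#' @param report A `batch_report` or `session_report`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_report_csv <- function(report, path) {
  table <- if (inherits(report, "batch_report")) {
    report$table
  } else {
    as.data.frame(report$measures)
  }
  cells <- vapply(seq_along(table), function(j) {
    unlist(lapply(table[[j]], fmt_report))
  }, FUN.VALUE = character(nrow(table)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(table))
  lines <- c(paste(names(table), collapse = ","),
             apply(cells, 1L, paste, collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write behavior events as CSV
#' @param events List of [event_series()] (or a single one).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_events_csv <- function(events, path) {
  if (inherits(events, "event_series")) events <- list(events)
  rows <- lapply(events, function(es) {
    if (!nrow(es$events)) return(NULL)
    data.frame(behavior = es$behavior, onset_s = es$events$onset_s,
               offset_s = es$events$offset_s,
               duration_s = es$events$duration_s)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(behavior = character(), onset_s = numeric(),
                     offset_s = numeric(), duration_s = numeric())
  }
  lines <- c("behavior,onset_s,offset_s,duration_s",
             if (nrow(df)) paste(df$behavior, fmt_report(df$onset_s),
                                 fmt_report(df$offset_s),
                                 fmt_report(df$duration_s), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
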