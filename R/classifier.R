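#' Configuration of the behavior classifier
#'
#' @param window_frames Odd number of frames per sample window (default 15,
#'   about 0.6 s at 25 fps: behaviors are recognized from short sequences
#'   of the skeletal representation, not single frames).
#' @param hidden_sizes Hidden layer widths of the fully connected network
#'   (default `c(256, 128)`).
#' @param epochs,batch_size,learning_rate Training schedule of the Adam
#'   optimizer.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(window_frames = 15L,
                              hidden_sizes = c(256L, 128L),
                              epochs = 30L, batch_size = 128L,
                              learning_rate = 1e-3, seed = 1L) {
  w <- as.integer(window_frames)
  if (w < 1L || w %% 2L == 0L) {
    stop_ctx("window_frames must be odd", class = "skeletrack_invalid")
  }
  structure(list(window_frames = w,
                 hidden_sizes = as.integer(hidden_sizes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Train the windowed frame classifier
#'
#' Trains a small fully connected network (two hidden layers, 256 and 128
#' units) on windowed skeletal feature samples with a softmax output over
#' the behavior labels.  The loss is cross-entropy weighted by inverse
#' class frequency, so rare behaviors are not drowned out by the dominant
#' background class.  Inputs are standardized per feature using statistics
#' of the training data only; the statistics travel with the model.
#'
#' @param train_videos List of videos, each a list with elements `features`
#'   (a `skeleton_feature_track` or feature matrix) and `labels` (per-frame
#'   character labels).
#' @param cfg A [classifier_config()].
#' @param labels Optional fixed label set (ordered); defaults to the sorted
#'   labels present in the training data.
#' @return An object of class `behavior_classifier`.
#' @export
train_classifier <- function(train_videos, cfg = classifier_config(),
                             labels = NULL) {
  stopifnot(length(train_videos) >= 1L, inherits(cfg, "classifier_config"))
  xs <- list(); ys <- list()
  schema_version <- NULL
  feature_names <- NULL
  for (v in train_videos) {
    wd <- make_windows(v$features, v$labels, cfg$window_frames)
    xs[[length(xs) + 1L]] <- wd$x
    ys[[length(ys) + 1L]] <- wd$y
    if (inherits(v$features, "skeleton_feature_track")) {
      schema_version <- v$features$schema_version
      feature_names <- v$features$feature_names
    }
  }
  X <- do.call(rbind, xs)
  y_chr <- unlist(ys)
  if (is.null(labels)) labels <- sort(unique(y_chr))
  if (length(labels) < 2L) {
    stop_ctx("training data contains a single class ('", labels,
             "'); need at least 2", class = "skeletrack_invalid")
  }
  if (!all(y_chr %in% labels)) {
    stop_ctx("labels present in data but not in the label set: ",
             paste(setdiff(unique(y_chr), labels), collapse = ", "),
             class = "skeletrack_invalid")
  }
  y <- match(y_chr, labels)
  mu <- colMeans(X)
  sg <- apply(X, 2L, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sg, "/")
  freq <- tabulate(y, nbins = length(labels))
  cw <- ifelse(freq > 0, sum(freq) / (length(labels) * pmax(freq, 1)), 0)
  net <- mlp_train(Xs, y, n_classes = length(labels),
                   hidden = cfg$hidden_sizes,
                   class_weights = cw, epochs = cfg$epochs,
                   batch_size = cfg$batch_size, lr = cfg$learning_rate,
                   seed = cfg$seed)
  structure(list(net = net, labels = labels,
                 window_frames = cfg$window_frames,
                 hidden_sizes = cfg$hidden_sizes,
                 normalization = list(mean = mu, sd = sg),
                 class_weights = cw,
                 schema_version = schema_version,
                 feature_names = feature_names,
                 seed = cfg$seed),
            class = "behavior_classifier")
}

#' @export
print.behavior_classifier <- function(x, ...) {
  cat(sprintf("<behavior_classifier> %s | window %d frames | hidden %s\n",
              paste(x$labels, collapse = " / "), x$window_frames,
              paste(x$hidden_sizes, collapse = "-")))
  invisible(x)
}

#' Predict per-frame behavior labels
#'
#' @param object A [train_classifier()] model.
#' @param features A `skeleton_feature_track` or feature matrix for one
#'   video.
#' @param type `"label"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Character vector of per-frame labels, or a probability matrix.
#' @export
predict.behavior_classifier <- function(object, features, type = "label",
                                        ...) {
  wd <- make_windows(features, NULL, object$window_frames)
  Xs <- sweep(sweep(wd$x, 2L, object$normalization$mean, "-"),
              2L, object$normalization$sd, "/")
  P <- mlp_predict_prob(object$net, Xs)
  colnames(P) <- object$labels
  if (identical(type, "prob")) return(P)
  object$labels[max.col(P, ties.method = "first")]
}

#' Segment predicted labels of one behavior into events
#'
#' @param pred Per-frame label vector.
#' @param behavior Behavior label to segment.
#' @param fps Frame rate.
#' @param min_duration_ms,merge_gap_ms Passed to [segment_events()].
#' @return An [event_series()].
#' @export
labels_to_events <- function(pred, behavior, fps,
                             min_duration_ms = 150, merge_gap_ms = 150) {
  segment_events(pred == behavior, fps, behavior = behavior,
                 min_duration_ms = min_duration_ms,
                 merge_gap_ms = merge_gap_ms)
}

#' Leave-one-video-out cross-validation
#'
#' For each of the k videos, trains a classifier on the other k - 1 and
#' evaluates on the held-out one: frame-to-frame accuracy against the
#' held-out labels, and per-behavior event counts for both prediction and
#' ground truth (events obtained with [segment_events()] under the default
#' 150 ms bout rules).
#'
#' @param videos List of >= 2 videos as in [train_classifier()].
#' @param cfg A [classifier_config()]; fold i trains with `seed + i`.
#' @param fps Frame rate used for event segmentation.
#' @param default_label Background label excluded from event counting.
#' @return A `lovo_result`: list of per-fold reports (each with
#'   `frame_accuracy`, `event_counts` data frame, `predicted` labels) plus
#'   aggregate `mean_accuracy` and `event_count_correlation` (Pearson r
#'   between predicted and true event counts over all folds and behaviors).
#' @export
leave_one_video_out <- function(videos, cfg = classifier_config(), fps = 25,
                                default_label = "none") {
  if (length(videos) < 2L) {
    stop_ctx("need at least 2 videos for leave-one-video-out",
             class = "skeletrack_invalid")
  }
  all_labels <- sort(unique(unlist(lapply(videos, `[[`, "labels"))))
  behaviors <- setdiff(all_labels, default_label)
  folds <- vector("list", length(videos))
  for (i in seq_along(videos)) {
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + i
    model <- train_classifier(videos[-i], fold_cfg, labels = all_labels)
    held <- videos[[i]]
    pred <- predict(model, held$features)
    acc <- mean(pred == held$labels)
    counts <- data.frame(behavior = behaviors,
                         predicted = NA_integer_, truth = NA_integer_)
    for (b in seq_along(behaviors)) {
      counts$predicted[b] <- n_events(labels_to_events(pred, behaviors[b], fps))
      counts$truth[b] <- n_events(labels_to_events(held$labels, behaviors[b], fps))
    }
    folds[[i]] <- list(video = i, frame_accuracy = acc,
                       event_counts = counts, predicted = pred)
  }
  counts_all <- do.call(rbind, lapply(folds, `[[`, "event_counts"))
  r <- if (nrow(counts_all) >= 3L &&
           stats::sd(counts_all$predicted) > 0 &&
           stats::sd(counts_all$truth) > 0) {
    pearson_correlation(counts_all$predicted, counts_all$truth)
  } else {
    NA_real_
  }
  structure(list(folds = folds,
                 mean_accuracy = mean(vapply(folds, `[[`, 0, "frame_accuracy")),
                 event_count_correlation = r,
                 event_counts = counts_all),
            class = "lovo_result")
}

#' @export
print.lovo_result <- function(x, ...) {
  cat(sprintf("<lovo_result> %d folds | mean frame accuracy %.4f | event-count r %.4f\n",
              length(x$folds), x$mean_accuracy, x$event_count_correlation))
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample standard deviation over the mean, in percent: the dispersion
#' measure used to compare scoring systems and raters.
#'
#' @param values Numeric vector (n >= 2, nonzero mean).
#' @return CV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 50
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) {
    stop_ctx("need at least 2 values", class = "skeletrack_domain")
  }
  m <- mean(values)
  if (m == 0) {
    stop_ctx("coefficient of variation undefined for zero mean",
             class = "skeletrack_domain")
  }
  stats::sd(values) / m * 100
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return r in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_ctx("need equal-length vectors of length >= 3",
             class = "skeletrack_domain")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ctx("correlation undefined for zero variance",
             class = "skeletrack_domain")
  }
  stats::cor(x, y, method = "pearson")
}

#' Save / load a trained classifier bundle
#'
#' The bundle is a single portable file holding weights, normalization
#' statistics, label set, window length and the feature schema version.
#'
#' @param model A `behavior_classifier`.
#' @param path File path (conventionally `.rds`).
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "behavior_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "behavior_classifier")) {
    stop_ctx("not a behavior_classifier bundle: ", path,
             class = "skeletrack_format")
  }
  model
}
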