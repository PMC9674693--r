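# Evaluation: confusion-set metrics (accuracy, precision, recall, F1),
# fold aggregation (mean and sample SD), and the study's experiment suite —
# stratified 3-fold cross-validation with strict train/test hygiene, the
# Raw/DN/DN+ denoising ablation, and the frequency-resolution sweep.

#' Classification metrics from true and predicted labels
#'
#' With T* the set of true positives-class members and T the detected set:
#' accuracy `A = (|T* int T| + |(T* un T)^c|) / |U|`, precision
#' `P = |T* int T| / |T|`, recall `R = |T* int T| / |T*|`, and
#' `F1 = 2PR / (P + R)`. Empty denominators yield 0 (conservative
#' convention).
#'
#' @param truth 0/1 vector of actual classes
#' @param predicted 0/1 vector of predicted classes, same length
#' @return object of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `f1` and the confusion `counts`
#' @export
compute_metrics <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (!all(c(truth, predicted) %in% c(0L, 1L))) stop("labels must be 0/1")
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  tn <- sum(truth == 0 & predicted == 0)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  structure(list(accuracy = (tp + tn) / length(truth), precision = p,
                 recall = r, f1 = f1,
                 counts = list(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("A %.2f  P %.2f  R %.2f  F1 %.2f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Aggregate per-fold metric reports
#'
#' Per-metric arithmetic mean and sample standard deviation (n - 1
#' denominator) over folds, computed from unrounded fold values.
#'
#' @param reports list of at least two `metrics_report`s
#' @return list with `mean` and `sd`, each holding the four metrics
#' @export
aggregate_folds <- function(reports) {
  if (length(reports) < 2)
    stop("at least 2 fold reports required for a standard deviation")
  for (r in reports) stopifnot(inherits(r, "metrics_report"))
  metrics <- c("accuracy", "precision", "recall", "f1")
  vals <- sapply(metrics, function(m) sapply(reports, `[[`, m))
  list(mean = as.list(colMeans(vals)),
       sd = as.list(apply(vals, 2, stats::sd)))
}

# default experiment options; any entry can be overridden per call
experiment_opts <- function(noise = noise_spec(),
                            ae_spec = NULL,
                            ae_train = ae_train_spec(),
                            tspec = classifier_train_spec(),
                            spec1d = conv1d_classifier_spec(),
                            spec2d = conv2d_classifier_spec(),
                            baseline = NULL,
                            stft = stft_spec(),
                            resolution = NULL,
                            resolution_method = "decimate",
                            threshold = 0.5) {
  list(noise = noise, ae_spec = ae_spec, ae_train = ae_train, tspec = tspec,
       spec1d = spec1d, spec2d = spec2d, baseline = baseline, stft = stft,
       resolution = resolution, resolution_method = resolution_method,
       threshold = threshold)
}

# opts$tspec may be a single classifier_train_spec or a named list keyed by
# representation (training schedules may differ per representation)
tspec_for <- function(tspec, rep_name) {
  if (inherits(tspec, "classifier_train_spec")) return(tspec)
  out <- tspec[[rep_name]]
  if (is.null(out)) stop("no training spec for representation ", rep_name)
  out
}

fit_predict <- function(feats_train, feats_test, y_train, model_family, opts,
                        fold_seed) {
  if (model_family %in% c("cnn", "cnn1d", "cnn2d")) {
    tspec <- tspec_for(opts$tspec, feats_train$representation)
    tspec$seed <- fold_seed
    if (feats_train$kind == "1d") {
      if (model_family == "cnn2d") stop("cnn2d requires the spectrogram representation")
      model <- train_1d_classifier(feats_train$x, y_train, opts$spec1d, tspec)
    } else {
      if (model_family == "cnn1d") stop("cnn1d requires a 1D representation")
      model <- train_2d_classifier(feats_train$x, y_train, opts$spec2d, tspec)
    }
    predict_labels(model, feats_test$x, opts$threshold)
  } else {
    bspec <- if (is.null(opts$baseline)) baseline_spec(model_family)
             else { s <- opts$baseline; s$family <- model_family; s }
    flat <- function(f) if (f$kind == "1d") f$x else
      matrix(f$x, dim(f$x)[1], prod(dim(f$x)[-1]))
    model <- train_baseline(flat(feats_train), y_train, bspec, seed = fold_seed)
    predict_labels(model, flat(feats_test), opts$threshold)
  }
}

#' Run a stratified k-fold cross-validated experiment
#'
#' For every fold the pipeline is fit on the training folds only: the
#' denoiser (unless `mode = "Raw"`) is trained on training signals, training
#' data are augmented with noisy replicas (`mode = "DN+"` only), features are
#' extracted, the classifier is trained, and the untouched test fold is
#' scored. Test signals are never augmented and never enter denoiser or
#' classifier training; this is asserted, not assumed.
#'
#' Ablation modes: `"Raw"` = no denoiser and no injection; `"DN"` = plain
#' autoencoder denoising only; `"DN+"` = denoising autoencoder trained with
#' Gaussian-corrupted inputs plus Gaussian-noise augmentation of the
#' classifier training set.
#'
#' @param set a [signal_set()] with two classes
#' @param representation one or more of "waveform", "spectrum",
#'   "spectrogram"; several representations share fold splits and per-fold
#'   denoisers
#' @param model_family "cnn" (dilated 1D/2D CNN chosen by representation),
#'   "cnn1d", "cnn2d", "svm", "logit" or "mlp"
#' @param mode ablation mode: "DN+", "DN" or "Raw"
#' @param k number of folds
#' @param seed experiment seed (fold shuffle, training seeds, noise draws)
#' @param opts option overrides; see arguments of the internal
#'   `experiment_opts()` (noise, autoencoder and classifier specs, STFT,
#'   resolution, threshold)
#' @return an `experiment_report` (or a named list of them, one per
#'   representation): per-fold metrics, `mean`, `sd`, the fold assignment and
#'   a config snapshot
#' @export
run_cv_experiment <- function(set, representation = "spectrum",
                              model_family = "cnn",
                              mode = c("DN+", "DN", "Raw"), k = 3L, seed = 1L,
                              opts = list()) {
  stopifnot(inherits(set, "signal_set"))
  mode <- match.arg(mode)
  representation <- match.arg(representation,
                              c("waveform", "spectrum", "spectrogram"),
                              several.ok = TRUE)
  o <- experiment_opts()
  for (nm in names(opts)) {
    if (!nm %in% names(o)) stop("unknown experiment option: ", nm)
    o[[nm]] <- opts[[nm]]
  }
  folds <- stratified_kfold(set, k, seed)
  y_all <- labels01(set)

  per_fold <- stats::setNames(
    replicate(length(representation), vector("list", k), simplify = FALSE),
    representation)
  for (f in seq_len(k)) {
    test_ids <- names(folds$fold_of)[folds$fold_of == f]
    train_ids <- names(folds$fold_of)[folds$fold_of != f]
    if (length(intersect(train_ids, test_ids)) > 0 ||
        length(union(train_ids, test_ids)) != length(set$ids))
      stop("internal error: fold assignment is not a partition")
    train <- subset_set(set, train_ids, role = "train")
    test <- subset_set(set, test_ids, role = "test")
    fold_seed <- (as.integer(seed) * 97L + f) %% .Machine$integer.max

    if (mode != "Raw") {
      ae_noise <- if (mode == "DN+") o$noise else noise_spec(sigma_n = 0, copies_per_signal = 0)
      ae <- train_autoencoder(train, spec = o$ae_spec, tspec = o$ae_train,
                              noise = ae_noise, seed = fold_seed)
      train <- denoise_set(ae, train)
      test <- denoise_set(ae, test)
    }
    if (mode == "DN+") {
      aug_noise <- o$noise
      aug_noise$seed <- fold_seed
      train <- augment_training_set(train, aug_noise)
      if (length(intersect(test$ids, train$ids)) > 0)
        stop("leakage: test ids entered the augmented training set")
    }
    y_train <- labels01(train)
    y_test <- labels01(test)
    for (rep_name in representation) {
      feats_train <- representation_features(train$signals, rep_name,
                                             stft = o$stft,
                                             resolution = o$resolution,
                                             method = o$resolution_method)
      feats_test <- representation_features(test$signals, rep_name,
                                            stft = o$stft,
                                            resolution = o$resolution,
                                            method = o$resolution_method)
      pred <- fit_predict(feats_train, feats_test, y_train, model_family, o,
                          fold_seed)
      per_fold[[rep_name]][[f]] <- compute_metrics(y_test, pred$label)
    }
  }

  reports <- lapply(representation, function(rep_name) {
    agg <- aggregate_folds(per_fold[[rep_name]])
    structure(list(representation = rep_name, model_family = model_family,
                   mode = mode, k = k, seed = seed,
                   per_fold = per_fold[[rep_name]],
                   mean = agg$mean, sd = agg$sd, folds = folds,
                   config = list(mode = mode, model_family = model_family,
                                 representation = rep_name, k = k, seed = seed,
                                 sigma_n = o$noise$sigma_n,
                                 copies = o$noise$copies_per_signal,
                                 resolution = o$resolution)),
              class = "experiment_report")
  })
  names(reports) <- representation
  if (length(reports) == 1) reports[[1]] else reports
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s / %s / %s, %d-fold (seed %d)\n",
              x$representation, x$model_family, x$mode, x$k, x$seed))
  for (f in seq_along(x$per_fold)) {
    m <- x$per_fold[[f]]
    cat(sprintf("  %d-Fold  A %.2f  F1 %.2f  P %.2f  R %.2f\n", f,
                m$accuracy, m$f1, m$precision, m$recall))
  }
  cat(sprintf("  Avg.    A %.2f  F1 %.2f  P %.2f  R %.2f\n", x$mean$accuracy,
              x$mean$f1, x$mean$precision, x$mean$recall))
  cat(sprintf("  S.D.    A %.2f  F1 %.2f  P %.2f  R %.2f\n", x$sd$accuracy,
              x$sd$f1, x$sd$precision, x$sd$recall))
  invisible(x)
}

#' Denoising ablation: Raw vs DN vs DN+
#'
#' Three [run_cv_experiment()] invocations sharing the same seed (hence
#' identical fold assignments), differing only in the ablation mode.
#'
#' @inheritParams run_cv_experiment
#' @return named list of reports keyed "Raw", "DN", "DN+"
#' @export
run_ablation <- function(set, representation = "spectrum",
                         model_family = "cnn", k = 3L, seed = 1L,
                         opts = list()) {
  out <- lapply(c("Raw", "DN", "DN+"), function(mode)
    run_cv_experiment(set, representation, model_family, mode = mode, k = k,
                      seed = seed, opts = opts))
  names(out) <- c("Raw", "DN", "DN+")
  fa <- lapply(out, function(r)
    if (inherits(r, "experiment_report")) r$folds$fold_of else r[[1]]$folds$fold_of)
  if (!all(sapply(fa[-1], identical, fa[[1]])))
    stop("internal error: ablation modes received different fold splits")
  out
}

#' Frequency-resolution sweep for spectrum vs spectrogram analysis
#'
#' For each resolution the frequency axis of both representations is reduced
#' with [reduce_resolution()] and a cross-validated experiment is run.
#' Resolutions exceeding a representation's available bins are skipped with a
#' warning.
#'
#' @inheritParams run_cv_experiment
#' @param resolutions frequency-bin counts (study sweep: 125 to 2000 in steps
#'   of 125)
#' @return long-format data.frame: resolution, representation, metric, value
#' @export
run_resolution_sweep <- function(set, model_family = "cnn",
                                 resolutions = seq(125L, 2000L, by = 125L),
                                 k = 3L, seed = 1L, opts = list()) {
  o <- experiment_opts()
  for (nm in names(opts)) o[[nm]] <- opts[[nm]]
  n <- ncol(set$signals)
  avail <- c(spectrum = n %/% 2 + 1,
             spectrogram = o$stft$window_length %/% 2 + 1)
  rows <- list()
  for (r in resolutions) {
    for (rep_name in c("spectrum", "spectrogram")) {
      if (r > avail[[rep_name]]) {
        warning(sprintf("resolution %d exceeds the %d available %s bins; skipped",
                        r, avail[[rep_name]], rep_name), call. = FALSE)
        next
      }
      oo <- o; oo$resolution <- r
      repc <- run_cv_experiment(set, rep_name, model_family, mode = "DN+",
                                k = k, seed = seed, opts = oo)
      for (m in c("accuracy", "precision", "recall", "f1"))
        rows[[length(rows) + 1]] <- data.frame(
          resolution = r, representation = rep_name, metric = m,
          value = repc$mean[[m]])
    }
  }
  if (length(rows) == 0) return(data.frame(resolution = integer(),
                                           representation = character(),
                                           metric = character(),
                                           value = numeric()))
  do.call(rbind, rows)
}

#' Write an experiment report as a CSV table
#'
#' One row per fold plus Avg. and S.D. rows (the layout of the study's
#' tables); values are written at full precision.
#'
#' @param report an `experiment_report`
#' @param path destination CSV path
#' @export
report_csv <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  rows <- lapply(seq_along(report$per_fold), function(f) {
    m <- report$per_fold[[f]]
    data.frame(fold = sprintf("%d-Fold", f), accuracy = m$accuracy,
               f1 = m$f1, precision = m$precision, recall = m$recall)
  })
  rows[[length(rows) + 1]] <- data.frame(fold = "Avg.",
    accuracy = report$mean$accuracy, f1 = report$mean$f1,
    precision = report$mean$precision, recall = report$mean$recall)
  rows[[length(rows) + 1]] <- data.frame(fold = "S.D.",
    accuracy = report$sd$accuracy, f1 = report$sd$f1,
    precision = report$sd$precision, recall = report$sd$recall)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
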