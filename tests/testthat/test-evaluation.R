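# Metrics against a direct set-arithmetic oracle, fold aggregation, and the
# cross-validation harness (on fast baseline models).

# independent confusion-set oracle: build the sets T*, T explicitly
metrics_oracle <- function(truth, pred) {
  u <- seq_along(truth)
  Tstar <- u[truth == 1]; Tdet <- u[pred == 1]
  tp <- length(intersect(Tstar, Tdet))
  p <- if (length(Tdet)) tp / length(Tdet) else 0
  r <- if (length(Tstar)) tp / length(Tstar) else 0
  list(accuracy = (tp + length(setdiff(u, union(Tstar, Tdet)))) / length(u),
       precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

test_that("metrics match the set-arithmetic oracle on random confusion tables", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    m <- compute_metrics(truth, pred)
    o <- metrics_oracle(truth, pred)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$precision, o$precision)
    expect_equal(m$recall, o$recall)
    expect_equal(m$f1, o$f1)
    # metric identities
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    if (m$precision + m$recall > 0)
      expect_lte(m$f1, (m$precision + m$recall) / 2 + 1e-12)
    expect_true(m$accuracy >= 0 && m$accuracy <= 1)
  }
})

test_that("a worked confusion table gives A=0.8, P=R=F1=2/3", {
  truth <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)   # tp=2 fp=1 fn=1 tn=6
  m <- compute_metrics(truth, pred)
  expect_equal(m$counts, list(tp = 2L, fp = 1L, fn = 1L, tn = 6L))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
})

test_that("zero-denominator metrics fall back to 0", {
  m <- compute_metrics(c(1, 1, 0), c(0, 0, 0))  # nothing detected
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
  m2 <- compute_metrics(c(0, 0, 0), c(0, 1, 0)) # no true positives exist
  expect_equal(m2$recall, 0)
  expect_error(compute_metrics(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("fold aggregation uses the sample (n-1) standard deviation", {
  mk <- function(f1) structure(list(accuracy = f1, precision = f1,
                                    recall = f1, f1 = f1,
                                    counts = list()), class = "metrics_report")
  agg <- aggregate_folds(list(mk(0.64), mk(1.00), mk(1.00)))
  expect_equal(agg$mean$f1, 0.88)
  expect_equal(agg$sd$f1, stats::sd(c(0.64, 1, 1)))
  expect_equal(round(agg$sd$f1, 2), 0.21)   # population SD would print 0.17
  expect_false(round(sqrt(2 / 3) * agg$sd$f1, 2) == 0.21)

  agg2 <- aggregate_folds(list(mk(0.5), mk(0.5), mk(0.5)))
  expect_equal(agg2$sd$accuracy, 0)
  expect_error(aggregate_folds(list(mk(0.5))), "at least 2")
})

test_that("cross-validation partitions the ids and is reproducible", {
  set <- tiny_set(n_per_class = 12, n = 128, seed = 8)
  r1 <- run_cv_experiment(set, "spectrum", "logit", mode = "Raw", k = 3,
                          seed = 5)
  r2 <- run_cv_experiment(set, "spectrum", "logit", mode = "Raw", k = 3,
                          seed = 5)
  expect_s3_class(r1, "experiment_report")
  expect_setequal(names(r1$folds$fold_of), set$ids)
  for (f in seq_len(3))
    expect_identical(unclass(r1$per_fold[[f]]), unclass(r2$per_fold[[f]]))
  expect_identical(r1$mean, r2$mean)
  expect_length(r1$per_fold, 3)
  for (m in c("accuracy", "precision", "recall", "f1"))
    expect_true(r1$mean[[m]] >= 0 && r1$mean[[m]] <= 1)
})

test_that("separable classes are classified nearly perfectly by the harness", {
  set <- tiny_set(n_per_class = 12, n = 128, seed = 3, contrast_ratio = 3)
  r <- run_cv_experiment(set, "spectrum", "logit", mode = "Raw", k = 3,
                         seed = 2)
  expect_gte(r$mean$accuracy, 0.9)
})

test_that("label permutation drives cross-validated accuracy to chance", {
  set <- tiny_set(n_per_class = 15, n = 128, seed = 3, contrast_ratio = 3)
  set.seed(99)
  set$labels <- sample(set$labels)
  set$meta$label <- set$labels
  r <- run_cv_experiment(set, "spectrum", "logit", mode = "Raw", k = 3,
                         seed = 2)
  expect_gte(r$mean$accuracy, 0.2)
  expect_lte(r$mean$accuracy, 0.8)
})

test_that("ablation modes share one fold assignment and report all three modes", {
  set <- tiny_set(n_per_class = 9, n = 128, seed = 6)
  opts <- list(ae_spec = autoencoder_spec(128, latent_dim = 16),
               ae_train = ae_train_spec(epochs = 1, learning_rate = 0.01),
               noise = noise_spec(0.1, 1))
  reps <- run_ablation(set, "spectrum", "logit", k = 3, seed = 4, opts = opts)
  expect_named(reps, c("Raw", "DN", "DN+"))
  expect_identical(reps$Raw$folds$fold_of, reps$DN$folds$fold_of)
  expect_identical(reps$Raw$folds$fold_of, reps$`DN+`$folds$fold_of)
})

test_that("the resolution sweep runs per resolution and skips impossible points", {
  set <- tiny_set(n_per_class = 9, n = 128, seed = 6)
  opts <- list(ae_spec = autoencoder_spec(128, latent_dim = 16),
               ae_train = ae_train_spec(epochs = 1, learning_rate = 0.01),
               noise = noise_spec(0.1, 1))
  expect_warning(
    res <- run_resolution_sweep(set, "logit", resolutions = c(10, 60), k = 3,
                                seed = 4, opts = opts),
    "skipped")
  # spectrum has 65 bins, spectrogram only 17: resolution 60 runs for the
  # spectrum alone, resolution 10 for both
  expect_equal(sum(res$representation == "spectrum"), 8)
  expect_equal(sum(res$representation == "spectrogram"), 4)
  expect_true(all(res$value >= 0 & res$value <= 1))
})

test_that("experiment reports serialize to the fold/Avg/SD table layout", {
  set <- tiny_set(n_per_class = 6, n = 128)
  r <- run_cv_experiment(set, "spectrum", "logit", mode = "Raw", k = 3,
                         seed = 1)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  report_csv(r, f)
  tab <- read.csv(f)
  expect_equal(tab$fold, c("1-Fold", "2-Fold", "3-Fold", "Avg.", "S.D."))
  expect_equal(tab$accuracy[4], mean(tab$accuracy[1:3]))
})
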