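# Dilated CNN classifiers (1D for waveform/spectrum, 2D for spectrogram) and
# the classical baselines (linear SVM, L2 logistic regression, MLP). The CNNs
# share one blueprint: seven dilated convolution layers (kernel 3, batch
# normalization, dropout after every conv), four max-pooling stages, and three
# fully connected layers ending in a sigmoid unit trained with binary
# cross-entropy, L2 regularization on weights and biases, and Xavier normal
# initialization.

#' Dilated 1D CNN classifier architecture
#'
#' @param filters seven conv-filter counts
#' @param dilations seven dilation rates
#' @param kernel kernel size (3, as in compact VGG-style nets)
#' @param fc_units widths of the two hidden fully connected layers (the third
#'   is the sigmoid output)
#' @param dropout_rate rate of the seven dropout layers
#' @param pool_after indices of the four conv layers followed by max pooling
#' @param batch_norm batch-normalize each conv layer
#' @param l2 L2 penalty coefficient on weights and biases
#' @return object of class `conv_classifier_spec`
#' @export
conv1d_classifier_spec <- function(filters = c(8, 8, 16, 16, 32, 32, 64),
                                   dilations = c(1, 1, 2, 2, 4, 4, 8),
                                   kernel = 3L, fc_units = c(256, 64),
                                   dropout_rate = 0.2,
                                   pool_after = c(2, 4, 6, 7),
                                   batch_norm = TRUE, l2 = 1e-4) {
  if (length(filters) != 7 || length(dilations) != 7)
    stop("the classifier has seven dilated conv layers")
  if (length(pool_after) != 4) stop("the classifier has four max pooling layers")
  if (length(fc_units) != 2) stop("two hidden fully connected layers expected")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(ndim = 1L, filters = as.integer(filters),
                 dilations = as.integer(dilations), kernel = as.integer(kernel),
                 fc_units = as.integer(fc_units), dropout_rate = dropout_rate,
                 pool_after = as.integer(pool_after),
                 batch_norm = isTRUE(batch_norm), l2 = l2),
            class = "conv_classifier_spec")
}

#' Dilated 2D CNN classifier architecture
#'
#' The 1D blueprint extended to two dimensions: 3x3 kernels and (2, 2)
#' pooling; otherwise identical structure.
#'
#' @inheritParams conv1d_classifier_spec
#' @return object of class `conv_classifier_spec`
#' @export
conv2d_classifier_spec <- function(filters = c(8, 8, 16, 16, 32, 32, 64),
                                   dilations = c(1, 1, 2, 2, 4, 4, 8),
                                   kernel = 3L, fc_units = c(256, 64),
                                   dropout_rate = 0.2,
                                   pool_after = c(2, 4, 6, 7),
                                   batch_norm = TRUE, l2 = 1e-4) {
  spec <- conv1d_classifier_spec(filters, dilations, kernel, fc_units,
                                 dropout_rate, pool_after, batch_norm, l2)
  spec$ndim <- 2L
  spec
}

#' Classifier training schedule
#'
#' Defaults are the study's best settings for both CNNs: learning rate 0.001,
#' batch size 15, 50 epochs, Adam, binary cross-entropy.
#'
#' @param epochs,learning_rate,batch_size optimization schedule
#' @param seed seed for initialization, shuffling and dropout
#' @return object of class `classifier_train_spec`
#' @export
classifier_train_spec <- function(epochs = 50L, learning_rate = 0.001,
                                  batch_size = 15L, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "classifier_train_spec")
}

#' Baseline model specification
#'
#' @param family "svm" (linear kernel), "logit" (L2-regularized logistic
#'   regression) or "mlp" (five hidden layers of 100 rectifier units, sigmoid
#'   output, cross-entropy loss)
#' @param svm_kernel SVM kernel; the study found the linear kernel best
#' @param mlp_hidden hidden layer widths of the MLP
#' @param mlp_epochs,mlp_batch_size,mlp_learning_rate MLP schedule (study:
#'   100 epochs, batch 12, rate 0.001)
#' @param logit_lambda ridge penalty of the logistic regression
#' @return object of class `baseline_spec`
#' @export
baseline_spec <- function(family = c("svm", "logit", "mlp"),
                          svm_kernel = "linear", mlp_hidden = rep(100L, 5),
                          mlp_epochs = 100L, mlp_batch_size = 12L,
                          mlp_learning_rate = 0.001, logit_lambda = 0.01) {
  family <- match.arg(family)
  structure(list(family = family, svm_kernel = svm_kernel,
                 mlp_hidden = as.integer(mlp_hidden),
                 mlp_epochs = as.integer(mlp_epochs),
                 mlp_batch_size = as.integer(mlp_batch_size),
                 mlp_learning_rate = mlp_learning_rate,
                 logit_lambda = logit_lambda), class = "baseline_spec")
}

check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2)
    stop("training data contains a single class")
  labels
}

build_conv_classifier_net <- function(spec, input_shape, seed) {
  layers <- list()
  for (i in 1:7) {
    layers <- c(layers, list(
      if (spec$ndim == 1L)
        layer_conv1d(spec$filters[i], spec$kernel, spec$dilations[i],
                     batch_norm = spec$batch_norm)
      else
        layer_conv2d(spec$filters[i], spec$kernel, spec$dilations[i],
                     batch_norm = spec$batch_norm),
      layer_dropout(spec$dropout_rate)))
    if (i %in% spec$pool_after)
      layers <- c(layers, list(
        if (spec$ndim == 1L) layer_maxpool1d() else layer_maxpool2d()))
  }
  layers <- c(layers, list(layer_flatten(),
                           layer_dense(spec$fc_units[1], "relu"),
                           layer_dense(spec$fc_units[2], "relu"),
                           layer_dense(1L, "linear")))
  nn_network(layers, input_shape = input_shape, seed = seed)
}

#' Train the dilated 1D CNN classifier
#'
#' @param features numeric matrix, one feature vector (waveform or spectrum)
#'   per row
#' @param labels 0/1 vector (1 = positive class)
#' @param spec a [conv1d_classifier_spec()]
#' @param tspec a [classifier_train_spec()]
#' @return object of class `cnn_classifier`
#' @export
train_1d_classifier <- function(features, labels,
                                spec = conv1d_classifier_spec(),
                                tspec = classifier_train_spec()) {
  stopifnot(inherits(spec, "conv_classifier_spec"), spec$ndim == 1L,
            inherits(tspec, "classifier_train_spec"))
  features <- as.matrix(features)
  labels <- check_binary_labels(labels)
  stopifnot(nrow(features) == length(labels))
  x <- array(features, c(nrow(features), ncol(features), 1L))
  net <- build_conv_classifier_net(spec, c(ncol(features), 1L), seed = tspec$seed)
  fit <- nn_fit(net, x, labels, loss = "bce", epochs = tspec$epochs,
                learning_rate = tspec$learning_rate,
                batch_size = tspec$batch_size, l2 = spec$l2, seed = tspec$seed)
  fit$net <- nn_recalibrate_bn(fit$net, x)
  structure(list(net = fit$net, history = fit$history, ndim = 1L,
                 input_shape = c(ncol(features), 1L), spec = spec),
            class = c("cnn_classifier", "echotype_model"))
}

#' Train the dilated 2D CNN classifier on spectrograms
#'
#' @param spectrograms array `n x bins x frames` (as produced by
#'   [representation_features()] for the spectrogram representation)
#' @param labels 0/1 vector
#' @param spec a [conv2d_classifier_spec()]
#' @param tspec a [classifier_train_spec()]
#' @return object of class `cnn_classifier`
#' @export
train_2d_classifier <- function(spectrograms, labels,
                                spec = conv2d_classifier_spec(),
                                tspec = classifier_train_spec()) {
  stopifnot(inherits(spec, "conv_classifier_spec"), spec$ndim == 2L,
            inherits(tspec, "classifier_train_spec"))
  if (length(dim(spectrograms)) != 3)
    stop("spectrograms must be an n x bins x frames array (uniform shapes)")
  labels <- check_binary_labels(labels)
  stopifnot(dim(spectrograms)[1] == length(labels))
  d <- dim(spectrograms)
  x <- array(spectrograms, c(d, 1L))
  net <- build_conv_classifier_net(spec, c(d[2], d[3], 1L), seed = tspec$seed)
  fit <- nn_fit(net, x, labels, loss = "bce", epochs = tspec$epochs,
                learning_rate = tspec$learning_rate,
                batch_size = tspec$batch_size, l2 = spec$l2, seed = tspec$seed)
  fit$net <- nn_recalibrate_bn(fit$net, x)
  structure(list(net = fit$net, history = fit$history, ndim = 2L,
                 input_shape = c(d[2], d[3], 1L), spec = spec),
            class = c("cnn_classifier", "echotype_model"))
}

#' Train a classical baseline on flattened features
#'
#' Baselines consume exactly the features the CNNs see (spectrograms are
#' flattened row-major), after the same denoising/augmentation upstream.
#'
#' @param features numeric matrix, one flattened feature vector per row
#' @param labels 0/1 vector
#' @param spec a [baseline_spec()]
#' @param seed seed (MLP training; SVM/logit fits are deterministic)
#' @return object of class `baseline_model`
#' @export
train_baseline <- function(features, labels, spec = baseline_spec(),
                           seed = 1L) {
  stopifnot(inherits(spec, "baseline_spec"))
  features <- as.matrix(features)
  labels <- check_binary_labels(labels)
  fit <- switch(spec$family,
    svm = e1071::svm(x = features, y = factor(labels, levels = c(0, 1)),
                     kernel = spec$svm_kernel, scale = FALSE),
    logit = {
      # glmnet requires >= 2 predictors; pad a zero column for 1D toy inputs
      x <- if (ncol(features) == 1) cbind(features, 0) else features
      glmnet::glmnet(x, labels, family = "binomial", alpha = 0,
                     lambda = spec$logit_lambda)
    },
    mlp = {
      layers <- lapply(spec$mlp_hidden, function(u) layer_dense(u, "relu"))
      layers <- c(layers, list(layer_dense(1L, "linear")))
      net <- nn_network(layers, input_shape = ncol(features), seed = seed)
      nn_fit(net, features, labels, loss = "bce", epochs = spec$mlp_epochs,
             learning_rate = spec$mlp_learning_rate,
             batch_size = spec$mlp_batch_size, seed = seed)
    })
  structure(list(fit = fit, family = spec$family, ncol = ncol(features),
                 spec = spec), class = c("baseline_model", "echotype_model"))
}

#' Predict class scores and labels
#'
#' Scores are probabilities of the positive class in `[0, 1]`; the label is 1
#' when `score >= threshold` (ties go to the positive class). Prediction is
#' deterministic.
#'
#' @param model a trained `cnn_classifier` or `baseline_model`
#' @param features matrix (1D/baseline) or `n x bins x frames` array (2D CNN)
#'   matching the training shape
#' @param threshold decision threshold, default 0.5
#' @return data.frame with columns `score` and `label`
#' @export
predict_labels <- function(model, features, threshold = 0.5) {
  UseMethod("predict_labels")
}

#' @export
predict_labels.cnn_classifier <- function(model, features, threshold = 0.5) {
  if (model$ndim == 1L) {
    features <- as.matrix(features)
    if (ncol(features) != model$input_shape[1])
      stop("feature length ", ncol(features), " does not match training length ",
           model$input_shape[1])
    x <- array(features, c(nrow(features), model$input_shape))
  } else {
    d <- dim(features)
    if (length(d) != 3 || any(d[2:3] != model$input_shape[1:2]))
      stop("spectrogram shape does not match the training shape")
    x <- array(features, c(d, 1L))
  }
  score <- as.numeric(stats::plogis(nn_predict(model$net, x)))
  data.frame(score = score, label = as.integer(score >= threshold))
}

#' @export
predict_labels.baseline_model <- function(model, features, threshold = 0.5) {
  features <- as.matrix(features)
  if (ncol(features) != model$ncol)
    stop("feature length ", ncol(features), " does not match training length ",
         model$ncol)
  score <- switch(model$family,
    svm = {
      dv <- attr(stats::predict(model$fit, features, decision.values = TRUE),
                 "decision.values")
      # orient the decision value toward the positive class
      s <- if (grepl("^0/1$", colnames(dv)[1])) -dv[, 1] else dv[, 1]
      as.numeric(stats::plogis(s))
    },
    logit = {
      x <- if (model$ncol == 1) cbind(features, 0) else features
      as.numeric(stats::predict(model$fit, x, type = "response"))
    },
    mlp = as.numeric(stats::plogis(nn_predict(model$fit$net, features))))
  data.frame(score = score, label = as.integer(score >= threshold))
}
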