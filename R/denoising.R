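# Gaussian noise injection / augmentation and the dilated-1D-convolutional
# denoising autoencoder. The autoencoder compresses a length-N signal through
# six dilated conv layers, three max-pooling stages and two fully connected
# layers into a latent vector Z (default |Z| = 1250), then restores length N
# with seven dilated conv layers and three nearest-neighbour upsampling
# stages. Training minimizes the reconstruction error of the clean signal
# from a noise-corrupted input (MAE by default; squared error optional).

#' Gaussian noise specification
#'
#' `sigma_n` is interpreted relative to each signal's maximum absolute
#' amplitude (signals are normalized to `[-1, 1]` before the autoencoder, so
#' for normalized signals it is an absolute standard deviation).
#'
#' @param sigma_n relative noise standard deviation (study best value: 0.1)
#' @param copies_per_signal noisy replicas per original during augmentation
#'   (study value: 10)
#' @param seed optional seed used by [augment_training_set()]
#' @return object of class `noise_spec`
#' @export
noise_spec <- function(sigma_n = 0.1, copies_per_signal = 10L, seed = NULL) {
  if (sigma_n < 0) stop("sigma_n must be >= 0")
  if (copies_per_signal < 0) stop("copies_per_signal must be >= 0")
  structure(list(sigma_n = sigma_n,
                 copies_per_signal = as.integer(copies_per_signal),
                 seed = seed), class = "noise_spec")
}

#' Add Gaussian noise to a signal (or each row of a matrix of signals)
#'
#' @param samples numeric vector or matrix (one signal per row)
#' @param sigma_n relative noise SD; the absolute SD is `sigma_n * scale`
#' @param scale reference scale; defaults to each signal's max |amplitude|
#' @param seed optional local seed
#' @return noisy signal(s), same shape
#' @export
inject_gaussian_noise <- function(samples, sigma_n, scale = NULL, seed = NULL) {
  if (sigma_n < 0) stop("sigma_n must be >= 0")
  if (sigma_n == 0) return(samples)
  with_local_seed(seed, {
    if (is.matrix(samples)) {
      s <- if (is.null(scale)) apply(abs(samples), 1, max) else rep_len(scale, nrow(samples))
      samples + stats::rnorm(length(samples)) * rep(sigma_n * s, ncol(samples))
    } else {
      s <- if (is.null(scale)) max(abs(samples)) else scale
      samples + stats::rnorm(length(samples), 0, sigma_n * s)
    }
  })
}

#' Augment a training set with noisy replicas
#'
#' Each original signal is kept and `copies_per_signal` Gaussian-corrupted
#' replicas carrying the original's label are appended, so the output holds
#' `(1 + copies) * n` signals with class proportions conserved exactly.
#' Refuses sets tagged as test data: augmentation belongs to training folds
#' only.
#'
#' @param set a [signal_set()] with role "train" (or untagged)
#' @param noise a [noise_spec()]
#' @return augmented [signal_set()]
#' @export
augment_training_set <- function(set, noise) {
  stopifnot(inherits(set, "signal_set"), inherits(noise, "noise_spec"))
  if (identical(set$role, "test"))
    stop("refusing to augment a test set: augmentation is training-only")
  if (noise$copies_per_signal == 0) return(set)
  n <- nrow(set$signals)
  reps <- noise$copies_per_signal
  out <- matrix(0, n * (1 + reps), ncol(set$signals))
  out[seq_len(n), ] <- set$signals
  ids <- set$ids
  labels <- set$labels
  with_local_seed(noise$seed, {
    for (r in seq_len(reps)) {
      rows <- n * r + seq_len(n)
      out[rows, ] <- inject_gaussian_noise(set$signals, noise$sigma_n)
      ids <- c(ids, paste0(set$ids, "_aug", r))
      labels <- c(labels, set$labels)
    }
  })
  meta <- set$meta[rep(seq_len(n), 1 + reps), , drop = FALSE]
  meta$id <- ids
  meta$parent_id <- rep(set$ids, 1 + reps)
  meta$is_augmented <- rep(c(FALSE, rep(TRUE, reps)), each = n)
  signal_set(out, labels, ids = ids, meta = meta,
             positive_label = set$positive_label, role = set$role)
}

#' Denoising autoencoder architecture specification
#'
#' @param n_samples signal length N the model is built for
#' @param latent_dim size of the latent vector Z; must be a multiple of
#'   `ceiling(N/8)` rounded up to the pooled length (N is zero-padded to a
#'   multiple of 8 so three factor-2 poolings are exact)
#' @param encoder_filters six conv-filter counts
#' @param encoder_dilations six dilation rates
#' @param decoder_filters seven conv-filter counts; the last must be 1
#' @param decoder_dilations seven dilation rates
#' @param kernel convolution kernel size
#' @param fc_hidden width of the first encoder fully connected layer
#' @return object of class `autoencoder_spec`
#' @export
autoencoder_spec <- function(n_samples, latent_dim = 1250,
                             encoder_filters = c(8, 8, 16, 16, 32, 32),
                             encoder_dilations = c(1, 2, 4, 8, 16, 32),
                             decoder_filters = c(32, 32, 16, 16, 8, 8, 1),
                             decoder_dilations = c(1, 2, 4, 8, 16, 32, 1),
                             kernel = 3L, fc_hidden = 2L * latent_dim) {
  if (length(encoder_filters) != 6 || length(encoder_dilations) != 6)
    stop("encoder has six dilated conv layers")
  if (length(decoder_filters) != 7 || length(decoder_dilations) != 7)
    stop("decoder has seven dilated conv layers")
  if (utils::tail(decoder_filters, 1) != 1)
    stop("last decoder layer must emit one channel")
  if (latent_dim <= 0) stop("latent_dim must be > 0")
  n_samples <- as.integer(n_samples)
  npad <- as.integer(ceiling(n_samples / 8) * 8)
  l8 <- npad %/% 8L
  if (latent_dim %% l8 != 0)
    stop(sprintf(paste0("latent_dim (%d) must be a multiple of the pooled ",
                        "length N/8 = %d (N padded to %d)"),
                 latent_dim, l8, npad))
  if (latent_dim >= n_samples)
    stop("latent_dim must be smaller than the signal length (bottleneck)")
  structure(list(n_samples = n_samples, npad = npad, latent_dim = as.integer(latent_dim),
                 encoder_filters = as.integer(encoder_filters),
                 encoder_dilations = as.integer(encoder_dilations),
                 decoder_filters = as.integer(decoder_filters),
                 decoder_dilations = as.integer(decoder_dilations),
                 kernel = as.integer(kernel), fc_hidden = as.integer(fc_hidden)),
            class = "autoencoder_spec")
}

#' Autoencoder training schedule
#'
#' Defaults are the study's best settings: 200 epochs, learning rate 0.01,
#' batch size 12, MAE loss, Adam.
#'
#' @param epochs,learning_rate,batch_size optimization schedule
#' @param loss "mae" (default) or "mse"
#' @return object of class `ae_train_spec`
#' @export
ae_train_spec <- function(epochs = 200L, learning_rate = 0.01,
                          batch_size = 12L, loss = c("mae", "mse")) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), loss = match.arg(loss)),
            class = "ae_train_spec")
}

build_autoencoder_net <- function(spec, seed) {
  ef <- spec$encoder_filters; ed <- spec$encoder_dilations
  df <- spec$decoder_filters; dd <- spec$decoder_dilations
  l8 <- spec$npad %/% 8L
  c0 <- spec$latent_dim %/% l8
  layers <- list(
    layer_conv1d(ef[1], spec$kernel, ed[1]), layer_conv1d(ef[2], spec$kernel, ed[2]),
    layer_maxpool1d(),
    layer_conv1d(ef[3], spec$kernel, ed[3]), layer_conv1d(ef[4], spec$kernel, ed[4]),
    layer_maxpool1d(),
    layer_conv1d(ef[5], spec$kernel, ed[5]), layer_conv1d(ef[6], spec$kernel, ed[6]),
    layer_maxpool1d(),
    layer_flatten(),
    layer_dense(spec$fc_hidden, "relu"),
    layer_dense(spec$latent_dim, "linear"),
    layer_reshape1d(l8, c0),
    layer_conv1d(df[1], spec$kernel, dd[1]), layer_conv1d(df[2], spec$kernel, dd[2]),
    layer_upsample1d(),
    layer_conv1d(df[3], spec$kernel, dd[3]), layer_conv1d(df[4], spec$kernel, dd[4]),
    layer_upsample1d(),
    layer_conv1d(df[5], spec$kernel, dd[5]), layer_conv1d(df[6], spec$kernel, dd[6]),
    layer_upsample1d(),
    layer_conv1d(df[7], spec$kernel, dd[7], activation = "linear")
  )
  nn_network(layers, input_shape = c(spec$npad, 1L), seed = seed)
}

pad_signals <- function(m, npad) {
  n <- ncol(m)
  if (n == npad) return(m)
  lo <- (npad - n) %/% 2L
  out <- matrix(0, nrow(m), npad)
  out[, lo + seq_len(n)] <- m
  out
}

#' Train the denoising autoencoder
#'
#' Signals are normalized per-signal to unit maximum amplitude, zero-padded to
#' a multiple of 8 and fed through the encoder-decoder with a fresh Gaussian
#' corruption of each input batch (standard deviation `noise$sigma_n`); the
#' reconstruction target is the uncorrupted signal. With `sigma_n = 0` this
#' reduces to a plain compression autoencoder.
#'
#' @param x training signals: a [signal_set()] (must not be tagged as test
#'   data) or a numeric matrix with one signal per row
#' @param spec an [autoencoder_spec()]; defaulted from the signal length when
#'   `NULL` (latent dimension = padded length / 8)
#' @param tspec an [ae_train_spec()]
#' @param noise a [noise_spec()] providing the corruption level
#' @param seed seed for initialization, shuffling and corruption draws
#' @return object of class `denoising_model` with `net`, `spec` and per-epoch
#'   training `history`
#' @export
train_autoencoder <- function(x, spec = NULL, tspec = ae_train_spec(),
                              noise = noise_spec(), seed = 1L) {
  if (inherits(x, "signal_set")) {
    if (identical(x$role, "test"))
      stop("refusing to train the denoiser on a test set")
    x <- x$signals
  }
  x <- as.matrix(x)
  if (is.null(spec)) {
    npad <- as.integer(ceiling(ncol(x) / 8) * 8)
    spec <- autoencoder_spec(ncol(x), latent_dim = npad %/% 8L)
  }
  stopifnot(inherits(spec, "autoencoder_spec"), inherits(tspec, "ae_train_spec"))
  if (ncol(x) != spec$n_samples)
    stop("signal length ", ncol(x), " does not match spec n_samples ", spec$n_samples)
  xn <- pad_signals(normalize_rows(x), spec$npad)
  xa <- array(xn, c(nrow(xn), spec$npad, 1L))
  net <- build_autoencoder_net(spec, seed = seed)
  corrupt <- if (noise$sigma_n > 0) {
    function(xb) xb + stats::rnorm(length(xb)) * noise$sigma_n
  } else NULL
  fit <- nn_fit(net, xa, xa, loss = tspec$loss, epochs = tspec$epochs,
                learning_rate = tspec$learning_rate,
                batch_size = tspec$batch_size, seed = seed, corrupt = corrupt)
  structure(list(net = fit$net, spec = spec, history = fit$history,
                 noise = noise), class = "denoising_model")
}

#' @export
print.denoising_model <- function(x, ...) {
  cat(sprintf("<denoising_model> N = %d, |Z| = %d, %d epochs, final loss %.5f\n",
              x$spec$n_samples, x$spec$latent_dim, length(x$history),
              utils::tail(x$history, 1)))
  invisible(x)
}

#' Denoise signals with a trained autoencoder
#'
#' Each signal is normalized, padded, reconstructed and rescaled back to its
#' input amplitude; the output has exactly the input length. Inference is
#' deterministic.
#'
#' @param model a trained `denoising_model`
#' @param samples numeric vector of the model's signal length, or a matrix of
#'   such rows
#' @return denoised signal(s), same shape as the input
#' @export
denoise_signal <- function(model, samples) {
  stopifnot(inherits(model, "denoising_model"))
  vec <- !is.matrix(samples)
  m <- if (vec) matrix(samples, 1) else samples
  if (ncol(m) != model$spec$n_samples)
    stop("input length ", ncol(m), " does not match the trained length ",
         model$spec$n_samples)
  s <- apply(abs(m), 1, max)
  s[s == 0] <- 1
  xa <- array(pad_signals(m / s, model$spec$npad),
              c(nrow(m), model$spec$npad, 1L))
  out <- nn_predict(model$net, xa)
  lo <- (model$spec$npad - model$spec$n_samples) %/% 2L
  out <- matrix(out, nrow(m), model$spec$npad)[, lo + seq_len(model$spec$n_samples),
                                               drop = FALSE]
  out <- out * s
  if (vec) drop(out) else out
}

#' Denoise every signal of a set
#' @param model a trained `denoising_model`
#' @param set a [signal_set()]
#' @return the set with denoised signals
#' @export
denoise_set <- function(model, set) {
  stopifnot(inherits(set, "signal_set"))
  set$signals <- denoise_signal(model, set$signals)
  set
}
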