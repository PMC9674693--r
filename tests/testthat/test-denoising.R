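# Noise injection, augmentation bookkeeping, and the denoising autoencoder.

test_that("zero-sigma injection is the identity", {
  x <- rnorm(100)
  expect_identical(inject_gaussian_noise(x, 0), x)
})

test_that("injected noise has the requested relative standard deviation", {
  set.seed(5)
  x <- sin(seq(0, 20 * pi, length.out = 1e5))   # unit-scale signal
  noisy <- inject_gaussian_noise(x, 0.1, seed = 8)
  expect_equal(stats::sd(noisy - x), 0.1, tolerance = 0.05)
  # scale-relative: doubling the amplitude doubles the noise SD
  noisy2 <- inject_gaussian_noise(2 * x, 0.1, seed = 8)
  expect_equal(stats::sd(noisy2 - 2 * x), 0.2, tolerance = 0.05)
})

test_that("noise injection is deterministic under a seed", {
  x <- rnorm(500)
  expect_identical(inject_gaussian_noise(x, 0.2, seed = 3),
                   inject_gaussian_noise(x, 0.2, seed = 3))
})

test_that("augmentation yields (1 + copies) x n records with labels conserved", {
  set <- tiny_set(n_per_class = 51, n = 64)     # 102 signals
  train <- subset_set(set, set$ids, role = "train")
  aug <- augment_training_set(train, noise_spec(0.1, 10, seed = 2))
  expect_equal(nrow(aug$signals), 1122)         # 11 x 102
  expect_equal(as.vector(table(aug$labels)), c(561, 561))
  # every replica carries its parent's label
  parent_label <- set$labels[match(aug$meta$parent_id, set$ids)]
  expect_identical(aug$labels, parent_label)
  # originals are retained unchanged
  expect_identical(aug$signals[seq_len(102), ], unname(train$signals))
})

test_that("augmentation with zero copies is the identity and test sets are refused", {
  set <- tiny_set(n_per_class = 3, n = 64)
  train <- subset_set(set, set$ids, role = "train")
  expect_identical(augment_training_set(train, noise_spec(0.1, 0)), train)
  test <- subset_set(set, set$ids, role = "test")
  expect_error(augment_training_set(test, noise_spec(0.1, 5)),
               "training-only")
})

test_that("autoencoder spec enforces the layer counts and bottleneck", {
  expect_error(autoencoder_spec(512, encoder_filters = c(8, 8)),
               "six dilated conv")
  expect_error(autoencoder_spec(512, decoder_filters = c(8, 8, 8)),
               "seven dilated conv")
  expect_error(autoencoder_spec(512, latent_dim = 100), "multiple")
  expect_error(autoencoder_spec(512, latent_dim = 512), "smaller")
  spec <- autoencoder_spec(512, latent_dim = 64)
  expect_equal(spec$npad, 512L)
  spec2 <- autoencoder_spec(500, latent_dim = 63)
  expect_equal(spec2$npad, 504L)     # padded to a multiple of 8
})

test_that("a short training run reduces the reconstruction loss", {
  set.seed(20)
  set <- tiny_set(n_per_class = 10, n = 256, seed = 20)
  spec <- autoencoder_spec(256, latent_dim = 32)
  model <- train_autoencoder(set, spec, ae_train_spec(epochs = 5,
                                                      learning_rate = 0.01),
                             noise_spec(0.1, 10), seed = 6)
  expect_length(model$history, 5)
  expect_lt(tail(model$history, 1), model$history[1])
})

test_that("denoising preserves length and is deterministic at inference", {
  set <- tiny_set(n_per_class = 4, n = 256)
  spec <- autoencoder_spec(256, latent_dim = 32)
  model <- train_autoencoder(set, spec, ae_train_spec(epochs = 1,
                                                      learning_rate = 0.01),
                             noise_spec(0.1, 10), seed = 1)
  out1 <- denoise_signal(model, set$signals[1, ])
  out2 <- denoise_signal(model, set$signals[1, ])
  expect_length(out1, 256)
  expect_true(all(is.finite(out1)))
  expect_identical(out1, out2)
  expect_error(denoise_signal(model, rnorm(100)), "length")
})

test_that("the denoiser refuses to train on data tagged as test folds", {
  set <- tiny_set(n_per_class = 4, n = 256)
  test <- subset_set(set, set$ids, role = "test")
  expect_error(train_autoencoder(test, autoencoder_spec(256, latent_dim = 32)),
               "test set")
})

test_that("autoencoder training is reproducible under a seed", {
  set <- tiny_set(n_per_class = 6, n = 256)
  spec <- autoencoder_spec(256, latent_dim = 32)
  m1 <- train_autoencoder(set, spec, ae_train_spec(epochs = 2,
                                                   learning_rate = 0.01),
                          noise_spec(0.1, 10), seed = 44)
  m2 <- train_autoencoder(set, spec, ae_train_spec(epochs = 2,
                                                   learning_rate = 0.01),
                          noise_spec(0.1, 10), seed = 44)
  expect_identical(m1$history, m2$history)
  expect_identical(denoise_signal(m1, set$signals[1, ]),
                   denoise_signal(m2, set$signals[1, ]))
})
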