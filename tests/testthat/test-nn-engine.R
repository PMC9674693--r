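# The network engine is validated against finite-difference gradients: for
# every trainable parameter of small 1D/2D networks the analytic gradient
# must match the numerical one.

numerical_gradient <- function(net, x, y, lossfun, i, p, eps = 1e-5) {
  g <- net$layers[[i]][[p]]
  for (j in seq_along(g)) {
    n1 <- net; n1$layers[[i]][[p]][j] <- n1$layers[[i]][[p]][j] + eps
    n2 <- net; n2$layers[[i]][[p]][j] <- n2$layers[[i]][[p]][j] - eps
    l1 <- lossfun(echotype:::nn_forward(n1, x, training = TRUE)$out, y)$loss
    l2 <- lossfun(echotype:::nn_forward(n2, x, training = TRUE)$out, y)$loss
    g[j] <- (l1 - l2) / (2 * eps)
  }
  g
}

expect_gradients_match <- function(net, x, y, lossfun, tol = 1e-6) {
  fw <- echotype:::nn_forward(net, x, training = TRUE)
  lv <- lossfun(fw$out, y)
  grads <- echotype:::nn_backward(fw$net, fw$cache, lv$grad)
  for (i in seq_along(net$layers)) {
    for (p in names(grads[[i]])) {
      ng <- numerical_gradient(fw$net, x, y, lossfun, i, p)
      ag <- grads[[i]][[p]]
      # scale-aware comparison; under batch norm the conv bias gradient is
      # exactly zero, so compare against max(1, |ng|)
      err <- max(abs(as.numeric(ag) - as.numeric(ng))) /
        max(1, max(abs(as.numeric(ng))))
      expect_lt(err, tol)
    }
  }
}

test_that("analytic gradients match finite differences for a dilated 1D conv net", {
  net <- echotype:::nn_network(list(
    echotype:::layer_conv1d(3, dilation = 2, batch_norm = TRUE),
    echotype:::layer_maxpool1d(),
    echotype:::layer_conv1d(4, batch_norm = TRUE),
    echotype:::layer_flatten(),
    echotype:::layer_dense(5, "relu"),
    echotype:::layer_dense(1, "linear")), input_shape = c(12, 2), seed = 3)
  set.seed(11)
  x <- array(rnorm(4 * 12 * 2), c(4, 12, 2))
  expect_gradients_match(net, x, c(0, 1, 1, 0), echotype:::loss_bce)
})

test_that("gradients match through the encoder-decoder path (dense bottleneck, upsampling)", {
  net <- echotype:::nn_network(list(
    echotype:::layer_conv1d(3),
    echotype:::layer_maxpool1d(),
    echotype:::layer_flatten(),
    echotype:::layer_dense(8, "relu"),
    echotype:::layer_dense(12, "linear"),
    echotype:::layer_reshape1d(6, 2),
    echotype:::layer_upsample1d(),
    echotype:::layer_conv1d(1, dilation = 2, activation = "linear")),
    input_shape = c(12, 1), seed = 4)
  set.seed(12)
  x <- array(rnorm(3 * 12), c(3, 12, 1))
  target <- array(rnorm(3 * 12), c(3, 12, 1))
  expect_gradients_match(net, x, target, echotype:::loss_mae)
  expect_gradients_match(net, x, target, echotype:::loss_mse)
})

test_that("analytic gradients match finite differences for a dilated 2D conv net", {
  net <- echotype:::nn_network(list(
    echotype:::layer_conv2d(3, dilation = 2, batch_norm = TRUE),
    echotype:::layer_maxpool2d(),
    echotype:::layer_conv2d(2),
    echotype:::layer_maxpool2d(),
    echotype:::layer_flatten(),
    echotype:::layer_dense(1, "linear")), input_shape = c(8, 10, 1), seed = 5)
  set.seed(13)
  x <- array(rnorm(3 * 80), c(3, 8, 10, 1))
  expect_gradients_match(net, x, c(1, 0, 1), echotype:::loss_bce)
})

test_that("shapes propagate through pooling, upsampling and flattening", {
  net <- echotype:::nn_network(list(
    echotype:::layer_conv1d(4),
    echotype:::layer_maxpool1d(),
    echotype:::layer_upsample1d(),
    echotype:::layer_flatten()), input_shape = c(20, 1), seed = 1)
  expect_equal(net$layers[[2]]$out_shape, c(10L, 4L))
  expect_equal(net$layers[[3]]$out_shape, c(20L, 4L))
  expect_equal(net$output_shape, 80L)
  x <- array(rnorm(2 * 20), c(2, 20, 1))
  out <- echotype:::nn_forward(net, x)$out
  expect_equal(dim(out), c(2L, 80L))
})

test_that("training reduces the loss and is reproducible under a seed", {
  set.seed(2)
  x <- array(rnorm(20 * 16), c(20, 16, 1))
  y <- rep(c(0, 1), 10)
  build <- function() echotype:::nn_network(list(
    echotype:::layer_conv1d(4, batch_norm = TRUE),
    echotype:::layer_maxpool1d(),
    echotype:::layer_flatten(),
    echotype:::layer_dense(1, "linear")), input_shape = c(16, 1), seed = 9)
  f1 <- echotype:::nn_fit(build(), x, y, "bce", epochs = 15,
                          learning_rate = 0.01, batch_size = 5, seed = 21)
  f2 <- echotype:::nn_fit(build(), x, y, "bce", epochs = 15,
                          learning_rate = 0.01, batch_size = 5, seed = 21)
  expect_lt(tail(f1$history, 1), f1$history[1])
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$layers[[1]]$W, f2$net$layers[[1]]$W)
})
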