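# Minimal feed-forward neural-network engine used by the denoising autoencoder,
# the dilated CNN classifiers and the MLP baseline. Convolutions are evaluated
# as im2col + BLAS matrix products; gradients are hand-derived and verified
# against finite differences in the test suite. Data layouts (column-major):
#   1D signals:     array (batch, length, channels)
#   2D spectrograms: array (batch, height, width, channels)
# All randomness goes through R's global RNG; callers seed it.

# ---- layer constructors -----------------------------------------------------

#' Dilated 1D convolution layer (kernel 3 unless overridden, "same" padding)
#'
#' @param filters number of output channels
#' @param kernel odd kernel size
#' @param dilation dilation rate (taps are `dilation` samples apart)
#' @param activation "relu" or "linear"
#' @param batch_norm apply batch normalization between convolution and activation
#' @return a layer specification for [nn_network()]
#' @keywords internal
layer_conv1d <- function(filters, kernel = 3L, dilation = 1L,
                         activation = c("relu", "linear"), batch_norm = FALSE) {
  stopifnot(filters >= 1, kernel %% 2 == 1, dilation >= 1)
  list(type = "conv1d", filters = as.integer(filters), kernel = as.integer(kernel),
       dilation = as.integer(dilation), activation = match.arg(activation),
       batch_norm = isTRUE(batch_norm))
}

#' @rdname layer_conv1d
#' @keywords internal
layer_conv2d <- function(filters, kernel = 3L, dilation = 1L,
                         activation = c("relu", "linear"), batch_norm = FALSE) {
  stopifnot(filters >= 1, kernel %% 2 == 1, dilation >= 1)
  list(type = "conv2d", filters = as.integer(filters), kernel = as.integer(kernel),
       dilation = as.integer(dilation), activation = match.arg(activation),
       batch_norm = isTRUE(batch_norm))
}

#' @keywords internal
layer_maxpool1d <- function() list(type = "maxpool1d")

#' @keywords internal
layer_maxpool2d <- function() list(type = "maxpool2d")

#' Nearest-neighbour temporal upsampling by a factor of 2
#' @keywords internal
layer_upsample1d <- function() list(type = "upsample1d")

#' @keywords internal
layer_flatten <- function() list(type = "flatten")

#' Reshape the flat feature vector to (length, channels); inverse of flatten
#' @keywords internal
layer_reshape1d <- function(length, channels)
  list(type = "reshape1d", length = as.integer(length), channels = as.integer(channels))

#' Fully connected layer
#' @keywords internal
layer_dense <- function(units, activation = c("relu", "linear")) {
  stopifnot(units >= 1)
  list(type = "dense", units = as.integer(units), activation = match.arg(activation))
}

#' Dropout layer (active during training only)
#' @keywords internal
layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate)
}

# ---- network construction ---------------------------------------------------

# Xavier (Glorot) normal initialization, applied to weights and biases alike.
xavier <- function(n, fan_in, fan_out) {
  stats::rnorm(n, 0, sqrt(2 / (fan_in + fan_out)))
}

#' Build a network: propagate shapes and initialize parameters
#'
#' @param layers list of layer specifications
#' @param input_shape integer vector, shape of one example without the batch
#'   dimension: `c(L, C)` for 1D, `c(H, W, C)` for 2D, `D` for flat input
#' @param seed integer seed for the parameter initialization
#' @return an object of class `nn_network`
#' @keywords internal
nn_network <- function(layers, input_shape, seed = 1L) {
  set.seed(as.integer(seed))
  shape <- as.integer(input_shape)
  for (i in seq_along(layers)) {
    lay <- layers[[i]]
    lay$in_shape <- shape
    shape <- switch(lay$type,
      conv1d = {
        stopifnot(length(shape) == 2)
        cin <- shape[2]; k <- lay$kernel
        lay$W <- matrix(xavier(k * cin * lay$filters, k * cin, k * lay$filters),
                        k * cin, lay$filters)
        lay$b <- xavier(lay$filters, k * cin, k * lay$filters)
        if (lay$batch_norm) {
          lay$gamma <- rep(1, lay$filters); lay$beta <- rep(0, lay$filters)
          lay$run_mean <- rep(0, lay$filters); lay$run_var <- rep(1, lay$filters)
        }
        c(shape[1], lay$filters)
      },
      conv2d = {
        stopifnot(length(shape) == 3)
        cin <- shape[3]; k <- lay$kernel
        lay$W <- matrix(xavier(k * k * cin * lay$filters, k * k * cin, k * k * lay$filters),
                        k * k * cin, lay$filters)
        lay$b <- xavier(lay$filters, k * k * cin, k * k * lay$filters)
        if (lay$batch_norm) {
          lay$gamma <- rep(1, lay$filters); lay$beta <- rep(0, lay$filters)
          lay$run_mean <- rep(0, lay$filters); lay$run_var <- rep(1, lay$filters)
        }
        c(shape[1], shape[2], lay$filters)
      },
      maxpool1d = {
        if (shape[1] < 2) stop("input too short for max pooling at layer ", i)
        c(shape[1] %/% 2L, shape[2])
      },
      maxpool2d = {
        if (shape[1] < 2 || shape[2] < 2)
          stop("input too small for 2D max pooling at layer ", i)
        c(shape[1] %/% 2L, shape[2] %/% 2L, shape[3])
      },
      upsample1d = c(shape[1] * 2L, shape[2]),
      flatten = prod(shape),
      reshape1d = {
        stopifnot(length(shape) == 1, shape == lay$length * lay$channels)
        c(lay$length, lay$channels)
      },
      dense = {
        stopifnot(length(shape) == 1)
        lay$W <- matrix(xavier(shape * lay$units, shape, lay$units), shape, lay$units)
        lay$b <- xavier(lay$units, shape, lay$units)
        lay$units
      },
      dropout = shape,
      stop("unknown layer type: ", lay$type)
    )
    lay$out_shape <- as.integer(shape)
    layers[[i]] <- lay
  }
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 output_shape = as.integer(shape)),
            class = "nn_network")
}

# ---- shared primitives ------------------------------------------------------
# im2col / col2im, per-column affine ops, ReLU and the fused Adam step live in
# src/ (see kernels.cpp, adam.cpp); the GEMMs go through BLAS from R.

bn_forward <- function(zmat, lay, training, momentum = 0.9,
                       recalibrate = FALSE) {
  if (training) {
    mu <- colMeans(zmat)
    va <- pmax(colMeans(zmat * zmat) - mu * mu, 0)
    invstd <- 1 / sqrt(va + 1e-5)
    xhat <- affine_cols_cpp(zmat, invstd, -mu * invstd)
    if (recalibrate) {
      # exact population statistics of the dropout-free cascade
      lay$run_mean <- mu
      lay$run_var <- va
    } else {
      lay$run_mean <- momentum * lay$run_mean + (1 - momentum) * mu
      lay$run_var <- momentum * lay$run_var + (1 - momentum) * va
    }
  } else {
    invstd <- 1 / sqrt(lay$run_var + 1e-5)
    xhat <- affine_cols_cpp(zmat, invstd, -lay$run_mean * invstd)
  }
  y <- affine_cols_cpp(xhat, lay$gamma, lay$beta)
  list(y = y, xhat = xhat, invstd = invstd, lay = lay)
}

bn_backward <- function(dy, xhat, invstd, gamma) {
  m <- nrow(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- affine_cols_cpp(dy, gamma, numeric(length(gamma)))
  # dx = invstd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)), per channel
  dx <- bn_backward_dx_cpp(dxhat, xhat, colSums(dxhat) / m,
                           colSums(dxhat * xhat) / m, invstd)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- forward / backward -----------------------------------------------------

#' Forward pass
#'
#' @param net `nn_network`
#' @param x batched input array (first dimension = batch)
#' @param training logical; enables dropout and batch-statistics normalization
#' @return list with `out` (batched output) and `cache` (for [nn_backward()]);
#'   `net` is returned too so batch-norm running statistics persist.
#' @keywords internal
nn_forward <- function(net, x, training = FALSE, recalibrate = FALSE) {
  cache <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    lay <- net$layers[[i]]
    B <- dim(x)[1]
    res <- switch(lay$type,
      conv1d = {
        L <- lay$in_shape[1]; C <- lay$in_shape[2]
        Xc <- im2col1d_cpp(x, B, L, C, lay$kernel, lay$dilation)
        z <- add_cols_cpp(Xc %*% lay$W, lay$b)
        cc <- list(x = x)
        if (lay$batch_norm) {
          bn <- bn_forward(z, lay, training, recalibrate = recalibrate)
          z <- bn$y; lay <- bn$lay
          cc$xhat <- bn$xhat; cc$invstd <- bn$invstd
        }
        if (lay$activation == "relu") z <- relu_fwd_cpp(z)
        cc$post <- z
        y <- z; dim(y) <- c(B, L, lay$filters)
        list(y = y, cc = cc, lay = lay)
      },
      conv2d = {
        H <- lay$in_shape[1]; W <- lay$in_shape[2]; C <- lay$in_shape[3]
        Xc <- im2col2d_cpp(x, B, H, W, C, lay$kernel, lay$dilation)
        z <- add_cols_cpp(Xc %*% lay$W, lay$b)
        cc <- list(x = x)
        if (lay$batch_norm) {
          bn <- bn_forward(z, lay, training, recalibrate = recalibrate)
          z <- bn$y; lay <- bn$lay
          cc$xhat <- bn$xhat; cc$invstd <- bn$invstd
        }
        if (lay$activation == "relu") z <- relu_fwd_cpp(z)
        cc$post <- z
        y <- z; dim(y) <- c(B, H, W, lay$filters)
        list(y = y, cc = cc, lay = lay)
      },
      maxpool1d = {
        L2 <- lay$out_shape[1]
        x1 <- x[, seq.int(1L, 2L * L2, 2L), , drop = FALSE]
        x2 <- x[, seq.int(2L, 2L * L2, 2L), , drop = FALSE]
        takes1 <- x1 >= x2
        y <- x1
        y[!takes1] <- x2[!takes1]
        dim(y) <- c(B, L2, lay$out_shape[2])
        list(y = y, cc = list(takes1 = takes1), lay = lay)
      },
      maxpool2d = {
        H2 <- lay$out_shape[1]; W2 <- lay$out_shape[2]
        ih <- seq.int(1L, 2L * H2, 2L); iw <- seq.int(1L, 2L * W2, 2L)
        cand <- list(
          x[, ih, iw, , drop = FALSE], x[, ih + 1L, iw, , drop = FALSE],
          x[, ih, iw + 1L, , drop = FALSE], x[, ih + 1L, iw + 1L, , drop = FALSE])
        best <- cand[[1]]; idx <- array(1L, dim(best))
        for (q in 2:4) {
          sel <- cand[[q]] > best
          best[sel] <- cand[[q]][sel]
          idx[sel] <- q
        }
        list(y = best, cc = list(idx = idx), lay = lay)
      },
      upsample1d = {
        L <- lay$in_shape[1]; C <- lay$in_shape[2]
        y <- array(0, c(B, 2L * L, C))
        y[, seq.int(1L, 2L * L, 2L), ] <- x
        y[, seq.int(2L, 2L * L, 2L), ] <- x
        list(y = y, cc = NULL, lay = lay)
      },
      flatten = {
        y <- x; dim(y) <- c(B, prod(lay$in_shape))
        list(y = y, cc = NULL, lay = lay)
      },
      reshape1d = {
        y <- x; dim(y) <- c(B, lay$length, lay$channels)
        list(y = y, cc = NULL, lay = lay)
      },
      dense = {
        z <- x %*% lay$W
        z <- add_cols_cpp(z, lay$b)
        if (lay$activation == "relu") z <- pmax(z, 0)
        list(y = z, cc = list(x = x, post = z), lay = lay)
      },
      dropout = {
        if (training && !recalibrate && lay$rate > 0) {
          mask <- (stats::runif(length(x)) >= lay$rate) / (1 - lay$rate)
          dim(mask) <- dim(x)
          list(y = x * mask, cc = list(mask = mask), lay = lay)
        } else {
          list(y = x, cc = list(mask = NULL), lay = lay)
        }
      }
    )
    x <- res$y
    cache[[i]] <- res$cc
    net$layers[[i]] <- res$lay
  }
  list(out = x, cache = cache, net = net)
}

#' Backward pass: gradient of the loss w.r.t. every parameter
#'
#' @param net `nn_network` (after the corresponding forward pass)
#' @param cache cache from [nn_forward()] run with `training = TRUE`
#' @param dout gradient of the loss w.r.t. the network output
#' @return list of per-layer gradient lists (`W`, `b`, `gamma`, `beta`)
#' @keywords internal
nn_backward <- function(net, cache, dout) {
  grads <- vector("list", length(net$layers))
  dx <- dout
  for (i in rev(seq_along(net$layers))) {
    lay <- net$layers[[i]]
    cc <- cache[[i]]
    B <- if (lay$type %in% c("flatten", "dense", "dropout", "reshape1d"))
      dim(dx)[1] else dim(dx)[1]
    g <- NULL
    dx <- switch(lay$type,
      conv1d = {
        L <- lay$in_shape[1]; C <- lay$in_shape[2]
        k <- lay$kernel; dil <- lay$dilation
        dz <- dx; dim(dz) <- c(B * L, lay$filters)
        if (lay$activation == "relu") dz <- relu_bwd_cpp(dz, cc$post)
        g <- list()
        if (lay$batch_norm) {
          bb <- bn_backward(dz, cc$xhat, cc$invstd, lay$gamma)
          g$gamma <- bb$dgamma; g$beta <- bb$dbeta
          dz <- bb$dx
        }
        Xc <- im2col1d_cpp(cc$x, B, L, C, k, dil)
        g$W <- crossprod(Xc, dz)
        g$b <- colSums(dz)
        dXc <- tcrossprod(dz, lay$W)      # (B*L, k*C)
        dprev <- col2im1d_cpp(dXc, B, L, C, k, dil)
        dim(dprev) <- c(B, L, C)
        dprev
      },
      conv2d = {
        H <- lay$in_shape[1]; W2 <- lay$in_shape[2]; C <- lay$in_shape[3]
        k <- lay$kernel; dil <- lay$dilation
        dz <- dx; dim(dz) <- c(B * H * W2, lay$filters)
        if (lay$activation == "relu") dz <- relu_bwd_cpp(dz, cc$post)
        g <- list()
        if (lay$batch_norm) {
          bb <- bn_backward(dz, cc$xhat, cc$invstd, lay$gamma)
          g$gamma <- bb$dgamma; g$beta <- bb$dbeta
          dz <- bb$dx
        }
        Xc <- im2col2d_cpp(cc$x, B, H, W2, C, k, dil)
        g$W <- crossprod(Xc, dz)
        g$b <- colSums(dz)
        dXc <- tcrossprod(dz, lay$W)
        dprev <- col2im2d_cpp(dXc, B, H, W2, C, k, dil)
        dim(dprev) <- c(B, H, W2, C)
        dprev
      },
      maxpool1d = {
        L2 <- lay$out_shape[1]; C <- lay$out_shape[2]
        dprev <- array(0, c(B, lay$in_shape[1], C))
        dprev[, seq.int(1L, 2L * L2, 2L), ] <- dx * cc$takes1
        dprev[, seq.int(2L, 2L * L2, 2L), ] <- dx * !cc$takes1
        dprev
      },
      maxpool2d = {
        H2 <- lay$out_shape[1]; W2 <- lay$out_shape[2]
        dprev <- array(0, c(B, lay$in_shape[1], lay$in_shape[2], lay$in_shape[3]))
        ih <- seq.int(1L, 2L * H2, 2L); iw <- seq.int(1L, 2L * W2, 2L)
        dprev[, ih, iw, ] <- dx * (cc$idx == 1L)
        dprev[, ih + 1L, iw, ] <- dx * (cc$idx == 2L)
        dprev[, ih, iw + 1L, ] <- dx * (cc$idx == 3L)
        dprev[, ih + 1L, iw + 1L, ] <- dx * (cc$idx == 4L)
        dprev
      },
      upsample1d = {
        L <- lay$in_shape[1]
        dx[, seq.int(1L, 2L * L, 2L), , drop = FALSE] +
          dx[, seq.int(2L, 2L * L, 2L), , drop = FALSE]
      },
      flatten = {
        dprev <- dx; dim(dprev) <- c(B, lay$in_shape)
        dprev
      },
      reshape1d = {
        dprev <- dx; dim(dprev) <- c(B, lay$in_shape)
        dprev
      },
      dense = {
        dz <- dx
        if (lay$activation == "relu") dz <- dz * (cc$post > 0)
        g <- list(W = crossprod(cc$x, dz), b = colSums(dz))
        tcrossprod(dz, lay$W)
      },
      dropout = {
        if (is.null(cc$mask)) dx else dx * cc$mask
      }
    )
    grads[i] <- list(g)   # keep NULL slots (grads[[i]] <- NULL would drop them)
  }
  grads
}

# ---- losses -----------------------------------------------------------------

# Binary cross-entropy on logits; returns loss and gradient w.r.t. logits.
loss_bce <- function(logits, y) {
  p <- 1 / (1 + exp(-logits))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  list(loss = -mean(y * log(p) + (1 - y) * log(1 - p)),
       grad = (p - y) / length(y))
}

loss_mae <- function(pred, target) {
  d <- pred - target
  list(loss = mean(abs(d)), grad = sign(d) / length(d))
}

loss_mse <- function(pred, target) {
  d <- pred - target
  list(loss = mean(d * d), grad = 2 * d / length(d))
}

# ---- optimization -----------------------------------------------------------

adam_init <- function(net) {
  lapply(net$layers, function(lay) {
    nm <- intersect(c("W", "b", "gamma", "beta"), names(lay))
    st <- lapply(nm, function(p) list(m = lay[[p]] * 0, v = lay[[p]] * 0))
    names(st) <- nm
    st
  })
}

# Parameters and moment buffers are updated in place (they are freshly
# allocated per fit and aliased nowhere else); the fused kernel makes one pass
# per parameter block.
adam_step <- function(net, grads, state, lr, t, l2 = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      adam_update_inplace_cpp(net$layers[[i]][[p]], g[[p]], st$m, st$v,
                              lr, beta1, beta2, eps, t,
                              if (p %in% c("W", "b")) l2 else 0)
    }
  }
  invisible(NULL)
}

take_batch <- function(x, idx) {
  nd <- length(dim(x))
  if (nd == 2) x[idx, , drop = FALSE]
  else if (nd == 3) x[idx, , , drop = FALSE]
  else x[idx, , , , drop = FALSE]
}

#' Train a network with Adam
#'
#' @param net `nn_network`
#' @param x batched input array
#' @param y target: 0/1 vector for `loss = "bce"`, array matching the output
#'   shape for `"mae"`/`"mse"`
#' @param loss loss name
#' @param epochs,learning_rate,batch_size optimization schedule
#' @param l2 L2 penalty coefficient applied to weights and biases
#' @param seed RNG seed covering shuffling, dropout and any target corruption
#' @param corrupt optional function applied to each input batch before the
#'   forward pass (used for denoising-autoencoder input corruption)
#' @return list with the trained `net` and per-epoch mean loss `history`
#' @keywords internal
nn_fit <- function(net, x, y, loss = c("bce", "mae", "mse"),
                   epochs = 10L, learning_rate = 1e-3, batch_size = 16L,
                   l2 = 0, seed = 1L, corrupt = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  lfun <- switch(loss, bce = loss_bce, mae = loss_mae, mse = loss_mse)
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1)
  set.seed(as.integer(seed))
  n <- dim(x)[1]
  state <- adam_init(net)
  history <- numeric(epochs)
  t <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    bl <- split(ord, ceiling(seq_along(ord) / batch_size))
    tot <- 0
    for (bidx in bl) {
      xb <- take_batch(x, bidx)
      yb <- if (loss == "bce") y[bidx] else take_batch(y, bidx)
      if (!is.null(corrupt)) xb <- corrupt(xb)
      fw <- nn_forward(net, xb, training = TRUE)
      net <- fw$net
      lv <- lfun(fw$out, yb)
      grads <- nn_backward(net, fw$cache, lv$grad)
      t <- t + 1L
      adam_step(net, grads, state, learning_rate, t, l2)
      tot <- tot + lv$loss * length(bidx)
    }
    history[ep] <- tot / n
    if (verbose) message(sprintf("epoch %d/%d loss %.6f", ep, epochs, history[ep]))
  }
  list(net = net, history = history)
}

#' Re-estimate batch-norm running statistics after training
#'
#' Dropout noise inflates the activation variances that batch normalization
#' records during training, which damps logits at inference (the batch-norm /
#' dropout variance shift). One dropout-free pass over (a subsample of) the
#' training data replaces the running statistics of every layer with the
#' exact population statistics of the dropout-free cascade.
#'
#' @param net trained `nn_network`
#' @param x training input array
#' @param max_examples cap on the number of examples used for the statistics
#' @return the network with recalibrated statistics
#' @keywords internal
nn_recalibrate_bn <- function(net, x, max_examples = 512L) {
  if (!any(sapply(net$layers, function(l) isTRUE(l$batch_norm)))) return(net)
  n <- dim(x)[1]
  if (n > max_examples) {
    idx <- round(seq(1L, n, length.out = max_examples))
    x <- take_batch(x, idx)
  }
  nn_forward(net, x, training = TRUE, recalibrate = TRUE)$net
}

#' Deterministic inference pass
#' @keywords internal
nn_predict <- function(net, x, batch_size = 64L) {
  n <- dim(x)[1]
  outs <- NULL
  for (start in seq.int(1L, n, batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    o <- nn_forward(net, take_batch(x, idx), training = FALSE)$out
    outs <- if (is.null(outs)) o else {
      if (is.matrix(o)) rbind(outs, o) else {
        comb <- array(0, c(dim(outs)[1] + dim(o)[1], dim(o)[-1]))
        nd <- length(dim(o))
        if (nd == 3) { comb[seq_len(dim(outs)[1]), , ] <- outs; comb[dim(outs)[1] + seq_len(dim(o)[1]), , ] <- o }
        else { comb[seq_len(dim(outs)[1]), , , ] <- outs; comb[dim(outs)[1] + seq_len(dim(o)[1]), , , ] <- o }
        comb
      }
    }
  }
  outs
}
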