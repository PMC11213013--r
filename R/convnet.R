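# Internal convolutional network: a stack of (conv, relu, maxpool2, dropout)
# blocks, flattened, optionally concatenated with scalar covariates, then a
# hidden dense layer and a linear output unit. Used with a linear output for
# the Wave 1 latency regressor and with a sigmoid + cross-entropy for the
# above/below-threshold classifier.

nn_convnet_init <- function(L_in, kernels, channels, hidden, n_covar = 0L) {
  stopifnot(length(kernels) == length(channels))
  layers <- list()
  L <- L_in
  c_prev <- 1L
  for (i in seq_along(kernels)) {
    layers[[paste0("conv", i)]] <- nn_conv_init(kernels[i], c_prev, channels[i])
    L <- (L - kernels[i] + 1L) %/% 2L
    c_prev <- channels[i]
  }
  flat <- L * c_prev
  layers$fc1 <- nn_dense_init(flat + n_covar, hidden)
  layers$fc2 <- nn_dense_init(hidden, 1L)
  list(layers = layers, kernels = kernels, channels = channels,
       L_in = L_in, flat = flat, hidden = hidden, n_covar = n_covar)
}

nn_convnet_params <- function(net) {
  out <- list()
  for (nm in names(net$layers)) {
    out[[paste0(nm, ".W")]] <- net$layers[[nm]]$W
    out[[paste0(nm, ".b")]] <- net$layers[[nm]]$b
  }
  out
}

nn_convnet_set_params <- function(net, params) {
  for (nm in names(net$layers)) {
    net$layers[[nm]]$W <- params[[paste0(nm, ".W")]]
    net$layers[[nm]]$b <- params[[paste0(nm, ".b")]]
  }
  net
}

# Forward pass. X: N x L_in (already standardized). covar: N x n_covar or
# NULL. Returns the linear output (N-vector) and, when training = TRUE, the
# caches needed for the backward pass.
nn_convnet_fwd <- function(net, X, covar = NULL, dropout = 0, training = FALSE) {
  caches <- list()
  A <- X
  L <- net$L_in
  c_prev <- 1L
  for (i in seq_along(net$kernels)) {
    nm <- paste0("conv", i)
    idx <- nn_conv_index(L, net$kernels[i], c_prev)
    cv <- nn_conv_fwd(A, net$layers[[nm]], idx)
    rl <- nn_relu_fwd(cv$out)
    pl <- nn_pool2_fwd(rl$out, cv$L_out, net$channels[i])
    dp <- nn_dropout_fwd(pl$out, dropout, training)
    caches[[nm]] <- list(idx = idx, cv = cv, rl = rl, pl = pl, dp = dp,
                         L_in = L)
    A <- dp$out
    L <- pl$Lh
    c_prev <- net$channels[i]
  }
  flat <- A
  if (net$n_covar > 0L) {
    stopifnot(!is.null(covar), ncol(covar) == net$n_covar)
    A <- cbind(flat, covar)
  }
  z1 <- sweep(A %*% net$layers$fc1$W, 2, net$layers$fc1$b, `+`)
  h <- nn_relu_fwd(z1)
  y <- as.numeric(sweep(h$out %*% net$layers$fc2$W, 2, net$layers$fc2$b, `+`))
  if (!training) return(list(y = y))
  caches$dense <- list(A = A, h = h)
  list(y = y, caches = caches)
}

# Backward pass from dL/dy (N-vector); returns gradients named like
# nn_convnet_params().
nn_convnet_bwd <- function(net, dy, caches) {
  grads <- list()
  h <- caches$dense$h
  A <- caches$dense$A
  dy <- matrix(dy, ncol = 1L)
  grads$fc2.W <- crossprod(h$out, dy)
  grads$fc2.b <- colSums(dy)
  dh <- nn_relu_bwd(dy %*% t(net$layers$fc2$W), h)
  grads$fc1.W <- crossprod(A, dh)
  grads$fc1.b <- colSums(dh)
  dA <- tcrossprod(dh, net$layers$fc1$W)
  if (net$n_covar > 0L) dA <- dA[, seq_len(net$flat), drop = FALSE]
  for (i in rev(seq_along(net$kernels))) {
    nm <- paste0("conv", i)
    cc <- caches[[nm]]
    dA <- nn_dropout_bwd(dA, cc$dp)
    dA <- nn_pool2_bwd(dA, cc$pl, cc$cv$L_out, net$channels[i])
    dA <- nn_relu_bwd(dA, cc$rl)
    bk <- nn_conv_bwd(dA, net$layers[[nm]], cc$cv, cc$idx, cc$L_in)
    grads[[paste0(nm, ".W")]] <- bk$dW
    grads[[paste0(nm, ".b")]] <- bk$db
    dA <- bk$dX
  }
  grads
}

# Mini-batch training loop shared by both models. loss_grad(y, target)
# returns list(loss, dy). Returns the trained net and the loss trace.
nn_convnet_train <- function(net, X, covar, target, loss_grad,
                             epochs, batch_size, lr, dropout, seed) {
  set.seed(seed)
  # re-draw initial weights under the seed for full determinism
  net2 <- nn_convnet_init(net$L_in, net$kernels, net$channels, net$hidden,
                          net$n_covar)
  net <- net2
  params <- nn_convnet_params(net)
  state <- nn_adam_init(params)
  N <- nrow(X)
  t_step <- 0L
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0
    for (b in seq_len(ceiling(N / batch_size))) {
      rows <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, N)]
      fw <- nn_convnet_fwd(net, X[rows, , drop = FALSE],
                           if (is.null(covar)) NULL else covar[rows, , drop = FALSE],
                           dropout = dropout, training = TRUE)
      lg <- loss_grad(fw$y, target[rows])
      ep_loss <- ep_loss + lg$loss * length(rows)
      grads <- nn_convnet_bwd(net, lg$dy, fw$caches)
      t_step <- t_step + 1L
      upd <- nn_adam_step(params, grads, state, lr, t_step)
      params <- upd$params
      state <- upd$state
      net <- nn_convnet_set_params(net, params)
    }
    losses[ep] <- ep_loss / N
  }
  list(net = net, losses = losses)
}
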