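# Minimal 1-D convolutional network engine (internal).
#
# Activations are stored as N x (L*C) matrices with channels stacked
# column-block-wise: column (c-1)*L + l holds sample l of channel c.
# Convolutions are evaluated by patch extraction (im2col) and one matrix
# multiply per layer; gradients retrace the same index maps. Everything is
# driven by base R's RNG so training is bit-reproducible under a seed.

nn_conv_init <- function(k, c_in, c_out) {
  # He-style fan-in scaling
  W <- matrix(stats::rnorm(k * c_in * c_out, sd = sqrt(2 / (k * c_in))),
              k * c_in, c_out)
  list(W = W, b = numeric(c_out), k = k, c_in = c_in, c_out = c_out)
}

nn_dense_init <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

# Patch-column index map for an L-sample, c_in-channel input and width-k
# kernel: entry [(c-1)*k + j, p] is the input column of kernel tap j,
# channel c, at output position p.
nn_conv_index <- function(L, k, c_in) {
  L_out <- L - k + 1L
  idx <- matrix(0L, k * c_in, L_out)
  for (c in seq_len(c_in)) for (j in seq_len(k)) {
    idx[(c - 1L) * k + j, ] <- (c - 1L) * L + seq_len(L_out) + j - 1L
  }
  idx
}

nn_conv_fwd <- function(X, layer, idx) {
  N <- nrow(X)
  L_out <- ncol(idx)
  kc <- nrow(idx)
  P <- array(X[, as.vector(idx)], c(N, kc, L_out))
  Pm <- matrix(aperm(P, c(1, 3, 2)), N * L_out, kc)
  Y <- sweep(Pm %*% layer$W, 2, layer$b, `+`)
  list(out = matrix(Y, N, L_out * layer$c_out), Pm = Pm, L_out = L_out)
}

nn_conv_bwd <- function(dY, layer, cache, idx, L_in) {
  N <- nrow(dY)
  L_out <- cache$L_out
  dYm <- matrix(dY, N * L_out, layer$c_out)
  dW <- crossprod(cache$Pm, dYm)
  db <- colSums(dYm)
  dPm <- tcrossprod(dYm, layer$W)                    # (N*L_out) x (k*c_in)
  dP <- array(dPm, c(N, L_out, nrow(idx)))
  dX <- matrix(0, N, L_in * layer$c_in)
  for (r in seq_len(nrow(idx))) {
    cols <- idx[r, ]
    dX[, cols] <- dX[, cols] + dP[, , r]
  }
  list(dX = dX, dW = dW, db = db)
}

nn_pool2_fwd <- function(X, L, C) {
  # width-2, stride-2 max pooling per channel; odd tail sample dropped
  N <- nrow(X)
  Lh <- L %/% 2L
  out <- matrix(0, N, Lh * C)
  mask <- matrix(FALSE, N, Lh * C)   # TRUE when the first of the pair won
  for (c in seq_len(C)) {
    a <- X[, (c - 1L) * L + 2L * seq_len(Lh) - 1L, drop = FALSE]
    b <- X[, (c - 1L) * L + 2L * seq_len(Lh), drop = FALSE]
    sel <- a >= b
    out[, (c - 1L) * Lh + seq_len(Lh)] <- ifelse(sel, a, b)
    mask[, (c - 1L) * Lh + seq_len(Lh)] <- sel
  }
  list(out = out, mask = mask, Lh = Lh)
}

nn_pool2_bwd <- function(dY, cache, L, C) {
  N <- nrow(dY)
  Lh <- cache$Lh
  dX <- matrix(0, N, L * C)
  for (c in seq_len(C)) {
    g <- dY[, (c - 1L) * Lh + seq_len(Lh), drop = FALSE]
    sel <- cache$mask[, (c - 1L) * Lh + seq_len(Lh), drop = FALSE]
    dX[, (c - 1L) * L + 2L * seq_len(Lh) - 1L] <- g * sel
    dX[, (c - 1L) * L + 2L * seq_len(Lh)] <- g * !sel
  }
  dX
}

nn_relu_fwd <- function(X) list(out = pmax(X, 0), mask = X > 0)
nn_relu_bwd <- function(dY, cache) dY * cache$mask

nn_dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- matrix(stats::runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(out = X * mask, mask = mask)
}
nn_dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

nn_adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

nn_adam_step <- function(params, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * grads[[nm]]
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * grads[[nm]]^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Per-trace standardization: zero mean, unit sd (sd floor avoids blowing up
# flat traces). Makes the networks amplitude-invariant.
nn_standardize_rows <- function(X) {
  mu <- rowMeans(X)
  s <- sqrt(rowMeans((X - mu)^2))
  s[s < 1e-12] <- 1
  (X - mu) / s
}
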