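#' Train the Wave 1 latency regressor
#'
#' A small 1-D convolutional network (two blocks of convolution, max pooling
#' and dropout, then two dense layers) regressing the Wave 1 peak time from a
#' 244-sample trace, minimizing squared error. Traces are standardized per
#' trace, so the regressor responds to waveform shape, not absolute
#' amplitude; targets are scaled by the window length during optimisation.
#' Training is bit-reproducible given `seed`.
#'
#' @param waveforms List of [abr_waveform()] objects on a common grid.
#' @param tau Numeric vector of ground-truth Wave 1 latencies (ms), one per
#'   waveform, within the recording window.
#' @param epochs,batch_size,lr,dropout Optimisation settings (Adam).
#' @param kernels,channels,hidden Architecture settings: kernel widths and
#'   channel counts of the convolution blocks, and the hidden dense width.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return An object of class `wave1_cnn` with a [predict()][predict.wave1_cnn]
#'   method.
#' @examples
#' cfg <- synth_config(frequencies = 8, noise_sd = 0.05)
#' corp <- synth_corpus(2, cfg, seed = 1)
#' sup <- corpus_suprathreshold(corp, min_sl = 10)
#' m <- train_wave1_cnn(sup$waveforms, sup$tau, epochs = 5, seed = 1)
#' predict(m, sup$waveforms[[1]])
#' @export
train_wave1_cnn <- function(waveforms, tau, epochs = 60, batch_size = 32,
                            lr = 1e-3, dropout = 0.25,
                            kernels = c(9L, 5L), channels = c(8L, 16L),
                            hidden = 32L, seed = 1L) {
  if (length(waveforms) < 20L)
    stop("insufficient data: at least 20 training traces are required")
  stopifnot(length(tau) == length(waveforms))
  ns <- vapply(waveforms, function(w) length(w$voltages), integer(1))
  if (length(unique(ns)) != 1L)
    stop("all training traces must share the canonical grid")
  dur <- waveforms[[1]]$duration
  t0 <- waveforms[[1]]$t0
  if (any(tau < t0 | tau > t0 + dur))
    stop("latency labels must lie within the recording window")
  X <- nn_standardize_rows(do.call(rbind, lapply(waveforms, `[[`, "voltages")))
  # z-scored target: keeps the squared-error gradients well scaled even
  # though latencies span only a fraction of the window
  y_mu <- mean(tau)
  y_sd <- max(stats::sd(tau), 1e-6)
  y <- (tau - y_mu) / y_sd
  net <- nn_convnet_init(ncol(X), kernels, channels, hidden, 0L)
  loss_grad <- function(pred, target) {
    d <- pred - target
    list(loss = mean(d^2), dy = 2 * d / length(d))
  }
  fit <- nn_convnet_train(net, X, NULL, y, loss_grad,
                          epochs = epochs, batch_size = batch_size,
                          lr = lr, dropout = dropout, seed = seed)
  structure(list(net = fit$net, losses = fit$losses, duration = dur, t0 = t0,
                 y_mu = y_mu, y_sd = y_sd,
                 n_samples = ncol(X), seed = seed,
                 config = list(epochs = epochs, batch_size = batch_size,
                               lr = lr, dropout = dropout, kernels = kernels,
                               channels = channels, hidden = hidden)),
            class = "wave1_cnn")
}

#' Predict Wave 1 latency
#'
#' @param object A `wave1_cnn` model.
#' @param newdata An [abr_waveform()], a list of them, or a numeric matrix
#'   (one trace per row).
#' @param ... Unused.
#' @return Numeric vector of latency estimates in ms, clamped to the
#'   recording window.
#' @export
predict.wave1_cnn <- function(object, newdata, ...) {
  X <- traces_to_matrix(newdata, object$n_samples)
  y <- nn_convnet_fwd(object$net, nn_standardize_rows(X))$y
  pmin(pmax(object$y_mu + y * object$y_sd, object$t0),
       object$t0 + object$duration)
}

#' @export
print.wave1_cnn <- function(x, ...) {
  cat(sprintf("<wave1_cnn> %d-sample input, conv blocks [%s] x [%s] ch, final loss %.3g (seed %d)\n",
              x$n_samples, paste(x$config$kernels, collapse = ","),
              paste(x$config$channels, collapse = ","),
              x$losses[length(x$losses)], x$seed))
  invisible(x)
}

traces_to_matrix <- function(newdata, n_samples) {
  X <- if (inherits(newdata, "abr_waveform")) {
    matrix(newdata$voltages, nrow = 1)
  } else if (is.list(newdata)) {
    do.call(rbind, lapply(newdata, `[[`, "voltages"))
  } else {
    as.matrix(newdata)
  }
  if (ncol(X) != n_samples)
    stop("shape error: expected ", n_samples, " samples per trace, got ", ncol(X))
  X
}

#' Save / load a trained model
#'
#' Models are written as plain-text versioned RDS-free files (dput format) so
#' checkpoints survive text-only archiving.
#'
#' @param model A `wave1_cnn` or `abr_classifier` object.
#' @param path File path.
#' @return `path` (save) or the restored object (load).
#' @export
save_abr_model <- function(model, path) {
  obj <- unclass(model)
  obj$.class <- class(model)
  obj$.format_version <- 1L
  dput(obj, file = path,
       control = c("keepNA", "keepInteger", "showAttributes", "hexNumeric"))
  invisible(path)
}

#' @rdname save_abr_model
#' @export
load_abr_model <- function(path) {
  obj <- dget(path)
  cls <- obj$.class
  obj$.class <- NULL
  obj$.format_version <- NULL
  structure(obj, class = cls)
}
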