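#' Grouped train/test split
#'
#' Splits waveforms at the (subject, frequency)-group level so that no
#' series straddles the split: a random `train_fraction` of groups goes to
#' training, the rest to test.
#'
#' @param waveforms List of [abr_waveform()] objects.
#' @param train_fraction Fraction of groups allocated to training (default
#'   0.8).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with integer index vectors `train` and `test` and the group
#'   key of each waveform (`groups`).
#' @export
grouped_split <- function(waveforms, train_fraction = 0.8, seed = 1L) {
  keys <- vapply(waveforms, function(w) paste(w$subject_id, w$frequency, sep = "\r"),
                 character(1))
  groups <- unique(keys)
  if (length(groups) < 2L)
    stop("split error: at least 2 (subject, frequency) groups are required")
  set.seed(seed)
  n_train <- round(train_fraction * length(groups))
  n_train <- min(max(n_train, 1L), length(groups) - 1L)
  train_groups <- sample(groups, n_train)
  list(train = which(keys %in% train_groups),
       test = which(!keys %in% train_groups),
       groups = keys)
}

#' Classifier design matrix
#'
#' 246-column design matrix: 244 voltages plus dB level and frequency. When
#' `warp` is `TRUE`, voltages are replaced by their elastically aligned
#' versions, series by series (`series_index` groups the rows).
#'
#' @param waveforms List of [abr_waveform()] objects on a common grid.
#' @param warp Align traces within series before extracting features.
#' @param series_index Grouping vector parallel to `waveforms`.
#' @return Numeric matrix, one row per waveform.
#' @export
abr_feature_matrix <- function(waveforms, warp = FALSE, series_index = NULL) {
  X <- do.call(rbind, lapply(waveforms, `[[`, "voltages"))
  if (warp) {
    if (is.null(series_index))
      stop("warped features require 'series_index' to group waveforms into series")
    for (g in unique(series_index)) {
      rows <- which(series_index == g)
      if (length(rows) >= 2L)
        X[rows, ] <- align_series(X[rows, , drop = FALSE],
                                  duration = waveforms[[rows[1]]]$duration)$aligned
    }
  }
  cbind(X,
        db_spl = vapply(waveforms, `[[`, numeric(1), "db_spl"),
        frequency = vapply(waveforms, `[[`, numeric(1), "frequency"))
}

#' Train an above/below-threshold waveform classifier
#'
#' Binary classification of single ABR waveforms as responsive (above
#' threshold) or not, from 246 features: the 244-sample trace plus stimulus
#' level and frequency. Three model kinds are supported: `"logistic"`
#' (ridge-regularised logistic regression), `"xgboost"` (gradient-boosted
#' trees) and `"cnn"` (a 1-D convolutional network; stimulus level and
#' frequency join the flattened convolutional features before the dense
#' layers). For the logistic and boosted-tree models the traces are
#' elastically warp-aligned within their series as a preprocessing step; the
#' network consumes raw traces.
#'
#' @param kind `"logistic"`, `"xgboost"` or `"cnn"`.
#' @param waveforms Training waveforms (canonical grid).
#' @param labels Logical or 0/1 vector: above threshold?
#' @param series_index Integer/character vector grouping waveforms into
#'   series (needed for warping; defaults to subject x frequency).
#' @param warp Warp-align traces (default: TRUE for logistic and xgboost,
#'   FALSE for cnn, matching each model's preprocessing contract).
#' @param features Optional precomputed 246-column design matrix from
#'   [abr_feature_matrix()]; when supplied, `waveforms` may be `NULL` and no
#'   warping is redone (useful to share one warped design between models).
#' @param seed Integer seed.
#' @param epochs,batch_size,lr,dropout,hidden CNN settings.
#' @param nrounds,max_depth,eta Boosted-tree settings.
#' @param lambda Ridge penalty of the logistic model.
#' @return An object of class `abr_classifier` with a
#'   [predict()][predict.abr_classifier] method returning probabilities.
#' @export
train_abr_classifier <- function(kind = c("logistic", "xgboost", "cnn"),
                                 waveforms, labels, series_index = NULL,
                                 warp = NULL, seed = 1L,
                                 epochs = 30, batch_size = 32, lr = 1e-3,
                                 dropout = 0.25, hidden = 32L,
                                 nrounds = 150, max_depth = 4, eta = 0.1,
                                 lambda = 1e-3, features = NULL) {
  kind <- match.arg(kind)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: training requires both classes")
  if (is.null(warp)) warp <- kind != "cnn"
  Xf <- if (!is.null(features)) {
    as.matrix(features)
  } else {
    if (is.null(series_index))
      series_index <- vapply(waveforms, function(w)
        paste(w$subject_id, w$frequency, sep = "\r"), character(1))
    abr_feature_matrix(waveforms, warp = warp, series_index = series_index)
  }
  nv <- ncol(Xf) - 2L
  model <- switch(kind,
    logistic = {
      mu <- colMeans(Xf); sdv <- apply(Xf, 2, stats::sd); sdv[sdv < 1e-12] <- 1
      Xs <- sweep(sweep(Xf, 2, mu), 2, sdv, `/`)
      set.seed(seed)
      fit <- glmnet::glmnet(Xs, labels, family = "binomial", alpha = 0,
                            lambda = lambda, standardize = FALSE)
      list(fit = fit, mu = mu, sd = sdv)
    },
    xgboost = {
      set.seed(seed)
      dtr <- xgboost::xgb.DMatrix(Xf, label = labels)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = eta, nthread = 1, seed = seed),
        data = dtr, nrounds = nrounds, verbose = 0)
      list(fit = fit)
    },
    cnn = {
      V <- nn_standardize_rows(Xf[, seq_len(nv), drop = FALSE])
      cov_raw <- Xf[, nv + (1:2), drop = FALSE]
      cmu <- colMeans(cov_raw); csd <- apply(cov_raw, 2, stats::sd)
      csd[csd < 1e-12] <- 1
      covar <- sweep(sweep(cov_raw, 2, cmu), 2, csd, `/`)
      net <- nn_convnet_init(nv, kernels = c(9L, 5L, 3L),
                             channels = c(8L, 16L, 16L), hidden = hidden,
                             n_covar = 2L)
      loss_grad <- function(z, target) {
        p <- 1 / (1 + exp(-z))
        eps <- 1e-12
        list(loss = -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps)),
             dy = (p - target) / length(z))
      }
      fit <- nn_convnet_train(net, V, covar, labels, loss_grad,
                              epochs = epochs, batch_size = batch_size,
                              lr = lr, dropout = dropout, seed = seed)
      list(net = fit$net, losses = fit$losses, cov_mu = cmu, cov_sd = csd)
    })
  structure(list(kind = kind, model = model, warp = warp, n_samples = nv,
                 seed = seed),
            class = "abr_classifier")
}

#' Predict response probabilities
#'
#' @param object An `abr_classifier`.
#' @param newdata An [abr_series()], a list of waveforms, or a 246-column
#'   feature matrix. For warped models a series (or `series_index`) is
#'   needed so traces can be aligned the same way as in training.
#' @param series_index Optional grouping for warping when `newdata` is a
#'   waveform list.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.abr_classifier <- function(object, newdata, series_index = NULL, ...) {
  Xf <- if (is.matrix(newdata)) {
    newdata
  } else {
    wfs <- if (inherits(newdata, "abr_series")) newdata$waveforms
           else if (inherits(newdata, "abr_waveform")) list(newdata)
           else newdata
    if (is.null(series_index))
      series_index <- vapply(wfs, function(w)
        paste(w$subject_id, w$frequency, sep = "\r"), character(1))
    abr_feature_matrix(wfs, warp = object$warp && length(wfs) >= 2L,
                       series_index = series_index)
  }
  if (ncol(Xf) != object$n_samples + 2L)
    stop("shape error: expected ", object$n_samples + 2L, " features, got ", ncol(Xf))
  nv <- object$n_samples
  p <- switch(object$kind,
    logistic = {
      Xs <- sweep(sweep(Xf, 2, object$model$mu), 2, object$model$sd, `/`)
      as.numeric(stats::predict(object$model$fit, newx = Xs, type = "response"))
    },
    xgboost = as.numeric(stats::predict(object$model$fit,
                                        xgboost::xgb.DMatrix(Xf))),
    cnn = {
      V <- nn_standardize_rows(Xf[, seq_len(nv), drop = FALSE])
      covar <- sweep(sweep(Xf[, nv + (1:2), drop = FALSE], 2,
                           object$model$cov_mu), 2, object$model$cov_sd, `/`)
      z <- nn_convnet_fwd(object$model$net, V, covar)$y
      1 / (1 + exp(-z))
    })
  pmin(pmax(p, 0), 1)
}

#' @rdname predict.abr_classifier
#' @param model An `abr_classifier`.
#' @export
classify <- function(model, newdata, series_index = NULL) {
  predict(model, newdata, series_index = series_index)
}

#' @export
print.abr_classifier <- function(x, ...) {
  cat(sprintf("<abr_classifier> kind: %s, warp-aligned inputs: %s, %d voltage features (seed %d)\n",
              x$kind, x$warp, x$n_samples, x$seed))
  invisible(x)
}

#' Classification and threshold metrics
#'
#' Standard binary metrics of a classifier on a labelled test set: accuracy,
#' true and false positive rates, area under the ROC curve and under the
#' precision-recall curve (step integration).
#'
#' @param labels 0/1 (or logical) true labels.
#' @param probs Predicted probabilities.
#' @param cutoff Call cutoff (default 0.5).
#' @return List with `accuracy`, `tpr`, `fpr`, `auroc`, `auprc`, and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_classifier <- function(labels, probs, cutoff = 0.5) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(labels) == length(probs), length(labels) > 0)
  if (length(unique(labels)) < 2L)
    stop("AUROC undefined: test set contains a single class")
  call <- as.integer(probs >= cutoff)
  tp <- sum(call == 1 & labels == 1); fp <- sum(call == 1 & labels == 0)
  tn <- sum(call == 0 & labels == 0); fn <- sum(call == 0 & labels == 1)
  auroc <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
  # precision-recall step integration over descending score cutoffs
  ord <- order(probs, decreasing = TRUE)
  l <- labels[ord]
  tps <- cumsum(l)
  prec <- tps / seq_along(l)
  rec <- tps / sum(l)
  auprc <- sum(diff(c(0, rec)) * prec)
  list(accuracy = (tp + tn) / length(labels),
       tpr = tp / (tp + fn), fpr = fp / (fp + tn),
       auroc = auroc, auprc = auprc,
       tp = tp, fp = fp, tn = tn, fn = fn)
}
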