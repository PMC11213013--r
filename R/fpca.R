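#' Functional PCA of a set of waveforms
#'
#' Eigen-decomposition of the sample covariance of curves observed on one
#' uniform grid. Scores are projections of the centered curves onto the
#' eigenfunctions; eigenfunction signs are fixed so that the largest-magnitude
#' loading of each component is positive (determinism).
#'
#' @param x An [abr_series()], an `abr_warp`, or a numeric matrix with one
#'   curve per row (>= 3 curves).
#' @param n_components Number of retained components (default 2; the first
#'   two typically capture ~95% of the variance of a well-formed series).
#' @param warp_first If `TRUE`, curves are elastically aligned with
#'   [align_series()] before the decomposition (default `FALSE`).
#' @return An object of class `abr_fpca`: `mean_curve`, `eigenfunctions`
#'   (columns, ordered), `eigenvalues` (all, non-increasing),
#'   `variance_explained` (fractions per retained component), `scores`
#'   (matrix, one row per curve), `degenerate` (TRUE when the curves carry
#'   no variance), `n_components`.
#' @export
abr_fpca <- function(x, n_components = 2L, warp_first = FALSE) {
  M <- if (inherits(x, "abr_series")) series_matrix(x)
       else if (inherits(x, "abr_warp")) x$aligned
       else as.matrix(x)
  k <- nrow(M)
  if (k < 3L) stop("rank error: FPCA requires at least 3 curves")
  if (n_components > k - 1L)
    stop("rank error: more components requested than the sample supports")
  if (warp_first && !inherits(x, "abr_warp")) M <- align_series(M)$aligned
  mu <- colMeans(M)
  C <- sweep(M, 2, mu)
  total_var <- sum(C^2) / (k - 1)
  if (total_var < 1e-24) {
    return(structure(list(mean_curve = mu,
                          eigenfunctions = matrix(0, ncol(M), n_components),
                          eigenvalues = numeric(min(k - 1, ncol(M))),
                          variance_explained = rep(0, n_components),
                          scores = matrix(0, k, n_components),
                          degenerate = TRUE, n_components = n_components),
                     class = "abr_fpca"))
  }
  sv <- svd(C)
  ev <- sv$d^2 / (k - 1)
  phi <- sv$v
  # deterministic sign: dominant loading positive
  for (j in seq_len(ncol(phi))) {
    i <- which.max(abs(phi[, j]))
    if (phi[i, j] < 0) phi[, j] <- -phi[, j]
  }
  scores <- C %*% phi[, seq_len(n_components), drop = FALSE]
  structure(list(mean_curve = mu,
                 eigenfunctions = phi[, seq_len(n_components), drop = FALSE],
                 eigenvalues = ev,
                 variance_explained = ev[seq_len(n_components)] / sum(ev),
                 scores = scores,
                 degenerate = FALSE, n_components = n_components),
            class = "abr_fpca")
}

#' @export
print.abr_fpca <- function(x, ...) {
  cat(sprintf("<abr_fpca> %d curves, %d components, variance explained %s\n",
              nrow(x$scores), x$n_components,
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " + ")))
  invisible(x)
}

#' Two-cluster assignment of principal component scores
#'
#' k-means with k = 2 (10 restarts, seeded) on the score matrix. The cluster
#' whose centroid has the larger Euclidean norm is labelled `"above"`
#' (responsive), the near-origin cluster `"below"`. Ties and degenerate
#' score sets (all points identical) yield all-`"below"`.
#'
#' @param scores Numeric matrix of scores (>= 2 rows).
#' @param seed Integer seed for the k-means restarts (default 0).
#' @param nstart Number of k-means restarts (default 10).
#' @return An object of class `abr_clusters`: `labels` (factor
#'   `above`/`below` per row), `centers`, `seed`, `degenerate`.
#' @export
cluster_scores <- function(scores, seed = 0L, nstart = 10L) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("clustering requires at least 2 score points")
  if (nrow(unique(scores)) < 2L) {
    return(structure(list(labels = factor(rep("below", nrow(scores)),
                                          levels = c("below", "above")),
                          centers = rbind(colMeans(scores)), seed = seed,
                          degenerate = TRUE), class = "abr_clusters"))
  }
  set.seed(seed)
  km <- stats::kmeans(scores, centers = 2L, nstart = nstart)
  norms <- sqrt(rowSums(km$centers^2))
  if (abs(norms[1] - norms[2]) < 1e-12) {
    warning("cluster centroid norms tie; labelling all waveforms 'below'")
    lab <- rep("below", nrow(scores))
  } else {
    above <- which.max(norms)
    lab <- ifelse(km$cluster == above, "above", "below")
  }
  structure(list(labels = factor(lab, levels = c("below", "above")),
                 centers = km$centers, seed = seed, degenerate = FALSE),
            class = "abr_clusters")
}

#' Unsupervised threshold estimation for one series
#'
#' Pipeline: optional elastic alignment, response-envelope compression,
#' functional PCA to two components, 2-means clustering of the scores, and
#' threshold extraction by monotone closure over the per-dB cluster calls.
#'
#' Two details make the clustering scale-free and robust. First, each curve
#' is rescaled to a saturating response envelope: with `r` the curve's RMS
#' and `sigma` the series noise floor (median absolute deviation of first
#' differences across curves), the curve is multiplied by `g(r) / r` where
#' `g(r) = 10 * sigma * u / (1 + u)` and `u = (r / (1.5 * sigma))^4`.
#' Noise-level curves (`r` near `sigma`) are shrunk toward zero while any
#' clear response saturates near a common scale, so 2-means separates noise
#' from response instead of splitting the amplitude growth ramp mid-way.
#' Second, clustering runs on uncentered projections onto the
#' eigenfunctions, so in a mixed series subthreshold waveforms sit near the
#' origin of score space (the near-zero cluster). Clustering is only
#' meaningful when the series actually mixes responsive and non-responsive
#' levels; homogeneous series are decided directly from the envelope:
#' when every curve's RMS exceeds `resp_rms_mult * sigma` all levels are
#' called responsive, and when no curve does the series is called
#' non-responsive.
#'
#' @param series An [abr_series()] spanning at least 4 levels.
#' @param warp Elastically align the curves first (default `TRUE`;
#'   alignment is an amplitude-analysis step and never feeds latency
#'   reporting).
#' @param seed Seed for the k-means restarts.
#' @param rule Threshold rule, see [extract_threshold()].
#' @param resp_rms_mult RMS multiple of the noise floor above which a curve
#'   is an unambiguous response (default 3).
#' @return An `abr_threshold` object (see [extract_threshold()]) with
#'   `method = "unsupervised"`.
#' @export
unsupervised_threshold <- function(series, warp = TRUE, seed = 0L,
                                   rule = c("monotone_closure", "first_positive"),
                                   resp_rms_mult = 3) {
  stopifnot(inherits(series, "abr_series"))
  rule <- match.arg(rule)
  dbs <- series_dbs(series)
  if (length(dbs) < 4L)
    stop("unsupervised threshold estimation requires a series spanning >= 4 levels")
  M <- series_matrix(series)
  sigma <- stats::median(apply(M, 1, function(v) stats::mad(diff(v)) / sqrt(2)))
  sigma <- max(sigma, 1e-9)
  if (warp) M <- align_series(M, duration = series$waveforms[[1]]$duration)$aligned
  r <- sqrt(rowMeans(M^2))
  clearly <- r >= resp_rms_mult * sigma
  if (all(clearly) || !any(clearly)) {
    # homogeneous series: clustering has no contrast to work with
    calls <- as.integer(rep(all(clearly), length(dbs)))
    return(extract_threshold_calls(dbs, calls, rule = rule,
                                   method = "unsupervised"))
  }
  u <- (r / (1.5 * sigma))^4
  gain <- ifelse(r > 1e-12, 10 * sigma * (u / (1 + u)) / r, 0)
  Mc <- M * gain
  fp <- abr_fpca(Mc, n_components = 2L)
  if (fp$degenerate) {
    calls <- stats::setNames(rep(0L, length(dbs)), dbs)
    return(new_abr_threshold(NA_real_, calls, "unsupervised", dbs))
  }
  scores_unc <- Mc %*% fp$eigenfunctions   # uncentered: noise ~ origin
  ca <- cluster_scores(scores_unc, seed = seed)
  calls <- as.integer(ca$labels == "above")
  extract_threshold_calls(dbs, calls, rule = rule, method = "unsupervised")
}
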