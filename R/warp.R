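#' Elastic alignment of an ABR series
#'
#' Registers the waveforms of one series (e.g. all levels of a frequency) so
#' that peaks and troughs line up in time. Curves are represented by their
#' square-root slope functions (SRSF) and each is warped onto a template by a
#' dynamic-programming search over monotone, endpoint-fixed warping
#' functions. The template is initialised as the highest-energy waveform of
#' the series (the cleanest response) and refined once as the cross-sectional
#' mean of the aligned curves.
#'
#' Alignment decouples amplitude from phase: a warped curve takes the same
#' values as the original, only at reparameterized times. Warped curves are
#' therefore appropriate for amplitude analysis and as classifier inputs, but
#' latencies must always be reported from unwarped traces.
#'
#' @param series An [abr_series()] (>= 2 waveforms on a common grid) or a
#'   numeric matrix with one curve per row.
#' @param iterations Template refinement passes (default 2: initial template,
#'   then one mean refinement).
#' @param lambda Roughness penalty per unit time on the warp slope; 0 is
#'   fully elastic, larger values bias toward the identity warp. Default
#'   0.01.
#' @param band_ms Maximum |gamma(t) - t| explored by the warp search, ms
#'   (a Sakoe-Chiba band; default 2.5 ms, generous for ABR latency
#'   shifts).
#' @param duration Window length in ms (taken from the series when given).
#' @return An object of class `abr_warp`: `aligned` (matrix of warped
#'   curves), `warps` (matrix; row i is `gamma_i` evaluated on the template
#'   grid, in ms), `template`, `times` (grid, ms), `duration`.
#' @export
align_series <- function(series, iterations = 2L, lambda = 0.01,
                         duration = 10, band_ms = 2.5) {
  if (inherits(series, "abr_series")) {
    M <- series_matrix(series)
    duration <- series$waveforms[[1]]$duration
  } else {
    M <- as.matrix(series)
  }
  k <- nrow(M)
  n <- ncol(M)
  if (k < 2L) stop("alignment requires at least 2 waveforms")
  dt <- duration / n
  times <- (seq_len(n) - 1) * dt
  grid <- seq_len(n) - 1
  const <- apply(M, 1, function(v) stats::sd(v) < 1e-12)
  if (all(const)) {
    warning("all waveforms constant; returning identity warps")
    return(structure(list(aligned = M,
                          warps = matrix(rep(times, k), k, byrow = TRUE),
                          template = colMeans(M), times = times,
                          duration = duration), class = "abr_warp"))
  }
  if (any(const))
    warning("constant waveform(s) in series; identity warp used for them")
  energy <- rowMeans(M^2)
  template <- M[which.max(energy), ]
  gam <- matrix(rep(grid, k), k, byrow = TRUE)
  aligned <- M
  for (it in seq_len(iterations)) {
    qT <- srsf(template, dt)
    for (i in seq_len(k)) {
      if (const[i]) { gam[i, ] <- grid; aligned[i, ] <- M[i, ]; next }
      g <- .dp_warp(qT, srsf(M[i, ], dt), lambda,
                    as.integer(ceiling(band_ms / dt)))
      gam[i, ] <- g
      aligned[i, ] <- stats::approx(grid, M[i, ], xout = g, rule = 2)$y
    }
    template <- colMeans(aligned)
  }
  structure(list(aligned = aligned, warps = gam * dt, template = template,
                 times = times, duration = duration),
            class = "abr_warp")
}

#' @export
print.abr_warp <- function(x, ...) {
  dev <- max(abs(sweep(x$warps, 2, x$times)))
  cat(sprintf("<abr_warp> %d curves on %d samples; max |gamma(t) - t| = %.3g ms\n",
              nrow(x$aligned), ncol(x$aligned), dev))
  invisible(x)
}

# Square-root slope function q = f' / sqrt(|f'|), with the derivative taken
# by central differences (one-sided at the ends).
srsf <- function(f, dt) {
  n <- length(f)
  df <- numeric(n)
  df[1] <- (f[2] - f[1]) / dt
  df[n] <- (f[n] - f[n - 1]) / dt
  df[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (2 * dt)
  sign(df) * sqrt(abs(df))
}

#' Warping-function features
#'
#' Subsamples each warping function at `n_points` times spanning the full
#' window, yielding monotone feature vectors that encode each waveform's
#' phase variability (usable as classifier covariates).
#'
#' @param result An `abr_warp` from [align_series()].
#' @param n_points Number of samples per warp.
#' @return Matrix with one row per curve; row i is `gamma_i` evaluated at
#'   `n_points` equispaced times in `[0, duration]` ms (endpoints fixed).
#' @export
warp_features <- function(result, n_points = 10L) {
  stopifnot(inherits(result, "abr_warp"))
  tq <- seq(0, result$duration, length.out = n_points)
  xs <- c(result$times, result$duration)
  t(apply(result$warps, 1, function(g)
    stats::approx(xs, c(g, result$duration), xout = tq)$y))
}

#' Apply a stored warp to a curve
#'
#' @param v Numeric curve on the template grid.
#' @param gamma_ms Warping function in ms on the same grid (one row of
#'   `warps`).
#' @param duration Window length, ms.
#' @return Warped curve `v(gamma(t))`.
#' @export
apply_warp <- function(v, gamma_ms, duration = 10) {
  n <- length(v)
  dt <- duration / n
  stats::approx(seq_len(n) - 1, v, xout = gamma_ms / dt, rule = 2)$y
}
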