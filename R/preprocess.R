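#' Preprocessing configuration
#'
#' @param target_samples Samples per window on the canonical grid (default
#'   244).
#' @param target_duration Window length in ms (default 10).
#' @param sigma Gaussian smoothing bandwidth in sample units (default 1.0).
#' @return A list of class `abr_preprocess_config`.
#' @export
preprocess_config <- function(target_samples = 244, target_duration = 10,
                              sigma = 1.0) {
  if (target_samples < 8) stop("'target_samples' must be >= 8")
  if (sigma <= 0) stop("'sigma' must be > 0")
  structure(list(target_samples = as.integer(target_samples),
                 target_duration = as.numeric(target_duration),
                 sigma = as.numeric(sigma)),
            class = "abr_preprocess_config")
}

#' Resample a waveform onto the canonical grid
#'
#' Piecewise-linear interpolation of the recorded trace at the canonical grid
#' times `t0 + i * target_duration / target_samples`, `i = 0, ..., n-1`.
#' Windows longer than `target_duration` are cropped; windows shorter than
#' `target_duration` are rejected (no extrapolation beyond the recorded
#' window). Because the grid is sampled at period `duration/n`, the final
#' grid time can exceed the input's last sample time by less than one input
#' sample period; the last recorded value is held over that sub-sample tail.
#'
#' @param w An [abr_waveform()] with at least 2 samples.
#' @param cfg A [preprocess_config()].
#' @return An [abr_waveform()] with `cfg$target_samples` samples over
#'   `cfg$target_duration` ms.
#' @export
resample_abr <- function(w, cfg = preprocess_config()) {
  stopifnot(inherits(w, "abr_waveform"))
  n_in <- length(w$voltages)
  if (n_in < 2L)
    stop("degenerate input: resampling requires at least 2 samples")
  if (w$duration < cfg$target_duration - 1e-9)
    stop("coverage error: input window (", w$duration,
         " ms) is shorter than the target window (", cfg$target_duration, " ms)")
  t_in <- abr_times(w)
  dt_out <- cfg$target_duration / cfg$target_samples
  t_out <- w$t0 + (seq_len(cfg$target_samples) - 1) * dt_out
  v_out <- stats::approx(t_in, w$voltages, xout = t_out, method = "linear",
                         rule = 2)$y
  abr_waveform(v_out, w$subject_id, w$frequency, w$db_spl,
               t0 = w$t0, duration = cfg$target_duration, source = w$source)
}

# Discrete Gaussian kernel used by smooth_abr(): truncation radius
# ceiling(4*sigma) samples, normalized to sum 1.
gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Reflect out-of-range indices about the edge samples (edge not duplicated):
# index 0 -> 2, index n+1 -> n-1, etc.
reflect_index <- function(i, n) {
  i <- abs(i - 1) + 1        # reflect about 1
  over <- i > n
  i[over] <- 2 * n - i[over] # reflect about n
  i
}

#' Gaussian-smooth a waveform
#'
#' Discrete Gaussian convolution with kernel radius `ceiling(4*sigma)` samples
#' and reflective boundary handling (indices mirrored about the first/last
#' sample). Smoothing is used to stabilize peak localization only; amplitudes
#' are always read from the unsmoothed trace.
#'
#' @param w An [abr_waveform()] or a bare numeric vector.
#' @param sigma Bandwidth in sample units (> 0).
#' @return Same type as `w`, smoothed.
#' @export
smooth_abr <- function(w, sigma = 1.0) {
  if (sigma <= 0) stop("'sigma' must be > 0")
  v <- if (inherits(w, "abr_waveform")) w$voltages else as.numeric(w)
  n <- length(v)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  ext <- v[reflect_index((1L - r):(n + r), n)]
  sm <- as.numeric(stats::filter(ext, k, method = "convolution", sides = 2))
  sm <- sm[(r + 1L):(r + n)]
  if (inherits(w, "abr_waveform")) {
    w$voltages <- sm
    w
  } else {
    sm
  }
}
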