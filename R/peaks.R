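#' Peak-search configuration
#'
#' Constants of the constrained local-extremum search that refines the
#' network's Wave 1 estimate and chains Waves 2-5. The defaults are exact
#' integer sample counts on the canonical 244-sample / 10-ms grid
#' (sample period 10/244 ms): 0.3689 ms = 9 samples, 0.7377 ms = 18 samples,
#' 0.5738 ms = 14 samples. Values in ms are snapped to whole samples so the
#' search is grid-exact.
#'
#' @param search_back_window ms before the network estimate at which the
#'   search starts (default 0.3689).
#' @param min_peak_separation Minimum separation between reported peaks, ms
#'   (default 0.7377).
#' @param min_trough_separation Minimum separation between reported troughs,
#'   ms (default 0.5738).
#' @param smoothing_sigma Gaussian bandwidth (samples) applied before the
#'   extremum search (default 1.0).
#' @param amplitude_mode `"peak_to_trough"` (default; wave amplitude is peak
#'   voltage minus following trough voltage) or `"peak_absolute"` (peak
#'   voltage alone).
#' @param n_waves Number of waves to report (default 5).
#' @return A list of class `abr_peak_config`.
#' @export
peak_find_config <- function(search_back_window = 0.3689,
                             min_peak_separation = 0.7377,
                             min_trough_separation = 0.5738,
                             smoothing_sigma = 1.0,
                             amplitude_mode = c("peak_to_trough", "peak_absolute"),
                             n_waves = 5L) {
  amplitude_mode <- match.arg(amplitude_mode)
  stopifnot(search_back_window > 0, min_peak_separation > 0,
            min_trough_separation > 0, smoothing_sigma > 0)
  structure(list(search_back_window = search_back_window,
                 min_peak_separation = min_peak_separation,
                 min_trough_separation = min_trough_separation,
                 smoothing_sigma = smoothing_sigma,
                 amplitude_mode = amplitude_mode,
                 n_waves = as.integer(n_waves)),
            class = "abr_peak_config")
}

# Strict local maxima of a vector (interior samples only, plateaus ignored).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
}

# Height-priority distance pruning: visit candidates from tallest to
# shortest (ties broken by smaller index) and keep each one only if no
# already-kept candidate lies within min_sep samples. This removes small
# ripples riding next to a genuine peak.
prune_by_distance <- function(idx, height, min_sep) {
  if (length(idx) == 0L) return(integer(0))
  ord <- order(-height, idx)
  kept <- integer(0)
  for (j in ord) {
    if (all(abs(idx[kept] - idx[j]) >= min_sep)) kept <- c(kept, j)
  }
  sort(idx[kept])
}

#' Refine a Wave 1 estimate into a full peak set
#'
#' The second step of the two-step peak finder. The raw trace is smoothed
#' (`cfg$smoothing_sigma`), the search window starts
#' `cfg$search_back_window` ms before the Wave 1 estimate `t_hat`, and all
#' strict local maxima/minima in the window are found by neighbour
#' comparison. Maxima are pruned so that reported peaks are at least
#' `cfg$min_peak_separation` ms apart (taller peaks win), minima likewise at
#' `cfg$min_trough_separation`; the first surviving maximum is the Wave 1
#' peak and subsequent maxima/minima alternate as Waves 2-5 peaks and their
#' troughs. All reported voltages are read from the unsmoothed trace at the
#' located samples.
#'
#' @param w An [abr_waveform()] (raw, unsmoothed).
#' @param t_hat Wave 1 latency estimate in ms (within the window).
#' @param cfg A [peak_find_config()].
#' @return An object of class `abr_peaks`: vectors `peak_latency`,
#'   `peak_voltage`, `trough_latency`, `trough_voltage`, `amplitude` (one
#'   entry per wave, `NA` when absent), plus `amplitude_mode` and a
#'   `validated` flag per wave (only Wave 1 is validated).
#' @export
fine_tune_peaks <- function(w, t_hat, cfg = peak_find_config()) {
  stopifnot(inherits(w, "abr_waveform"))
  v <- w$voltages
  n <- length(v)
  dt <- w$duration / n
  if (!is.finite(t_hat) || t_hat < w$t0 || t_hat > w$t0 + w$duration)
    stop("'t_hat' must lie within the recording window")
  sm <- smooth_abr(v, cfg$smoothing_sigma)
  back <- max(1L, as.integer(round(cfg$search_back_window / dt)))
  sep_p <- max(1L, as.integer(round(cfg$min_peak_separation / dt)))
  sep_t <- max(1L, as.integer(round(cfg$min_trough_separation / dt)))
  ihat <- 1L + as.integer(round((t_hat - w$t0) / dt))
  start <- min(max(1L, ihat - back), n)

  seg <- sm[start:n]
  pk <- local_maxima(seg)
  pk <- prune_by_distance(pk, seg[pk], sep_p)
  if (length(pk) == 0L) {
    cond <- structure(class = c("abr_no_peak", "error", "condition"),
                      list(message = "no local maximum in the search range",
                           call = sys.call(-1)))
    stop(cond)
  }
  tr <- local_maxima(-seg)
  tr <- prune_by_distance(tr, -seg[tr], sep_t)

  nw <- cfg$n_waves
  peak_idx <- rep(NA_integer_, nw)
  trough_idx <- rep(NA_integer_, nw)
  use <- pk[seq_len(min(nw, length(pk)))]
  peak_idx[seq_along(use)] <- use + start - 1L
  for (k in seq_len(nw)) {
    if (is.na(peak_idx[k])) next
    lo <- peak_idx[k] - start + 1L
    hi <- if (k < nw && !is.na(peak_idx[k + 1L])) peak_idx[k + 1L] - start + 1L else length(seg) + 1L
    cand <- tr[tr > lo & tr < hi]
    if (length(cand)) trough_idx[k] <- cand[1L] + start - 1L
  }

  idx_time <- function(i) ifelse(is.na(i), NA_real_, w$t0 + (i - 1L) * dt)
  idx_volt <- function(i) ifelse(is.na(i), NA_real_, v[ifelse(is.na(i), 1L, i)])
  peak_voltage <- idx_volt(peak_idx)
  trough_voltage <- idx_volt(trough_idx)
  amplitude <- if (cfg$amplitude_mode == "peak_to_trough")
    peak_voltage - trough_voltage else peak_voltage
  structure(list(
    peak_index = peak_idx, trough_index = trough_idx,
    peak_latency = idx_time(peak_idx), peak_voltage = peak_voltage,
    trough_latency = idx_time(trough_idx), trough_voltage = trough_voltage,
    amplitude = amplitude,
    amplitude_mode = cfg$amplitude_mode,
    validated = c(TRUE, rep(FALSE, nw - 1L))
  ), class = "abr_peaks")
}

#' @export
print.abr_peaks <- function(x, ...) {
  cat("<abr_peaks>\n")
  df <- data.frame(wave = seq_along(x$peak_latency),
                   peak_ms = round(x$peak_latency, 4),
                   peak_uv = round(x$peak_voltage, 4),
                   trough_ms = round(x$trough_latency, 4),
                   amplitude_uv = round(x$amplitude, 4),
                   validated = x$validated)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Detect peaks with the two-step pipeline
#'
#' Composition of the Wave 1 latency regressor and [fine_tune_peaks()]. When
#' no trained model is supplied, the Wave 1 seed is the location of the
#' global maximum of the smoothed trace (adequate for clean recordings; a
#' trained [train_wave1_cnn()] model is the intended path).
#'
#' @param w An [abr_waveform()] on the canonical grid.
#' @param model A `wave1_cnn` model from [train_wave1_cnn()], or `NULL`.
#' @param cfg A [peak_find_config()].
#' @return An `abr_peaks` object; errors with class `abr_no_peak` when the
#'   search range contains no local maximum.
#' @export
detect_peaks <- function(w, model = NULL, cfg = peak_find_config()) {
  t_hat <- if (is.null(model)) {
    sm <- smooth_abr(w$voltages, cfg$smoothing_sigma)
    abr_times(w)[which.max(sm)]
  } else {
    predict(model, w)
  }
  fine_tune_peaks(w, t_hat, cfg)
}

#' Signed peak-estimation errors
#'
#' Signed differences between estimated and ground-truth Wave 1 latency and
#' amplitude: `e_tau = tau_est - tau_true` (ms) and `e_a = a_est - a_true`
#' (microvolts).
#'
#' @param est An `abr_peaks` object with Wave 1 present.
#' @param tau_true Ground-truth Wave 1 latency, ms.
#' @param a_true Ground-truth Wave 1 amplitude, microvolts (optional).
#' @return A list with `e_tau` and `e_a` (`NA` if `a_true` missing).
#' @export
compute_errors <- function(est, tau_true, a_true = NA_real_) {
  if (is.na(est$peak_latency[1]))
    stop("undefined error record: Wave 1 absent from the estimate")
  if (is.na(tau_true)) stop("undefined error record: ground truth absent")
  list(e_tau = est$peak_latency[1] - tau_true,
       e_a = if (is.na(a_true)) NA_real_ else est$amplitude[1] - a_true)
}

#' Summarise a batch of error records
#'
#' @param errors List of records from [compute_errors()].
#' @return A data.frame with mean, standard deviation and standard error of
#'   `e_tau` and `e_a`.
#' @export
summarize_errors <- function(errors) {
  et <- vapply(errors, `[[`, numeric(1), "e_tau")
  ea <- vapply(errors, `[[`, numeric(1), "e_a")
  one <- function(x) {
    x <- x[!is.na(x)]
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
               se = stats::sd(x) / sqrt(length(x)))
  }
  rbind(cbind(metric = "e_tau", one(et)), cbind(metric = "e_a", one(ea)))
}
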