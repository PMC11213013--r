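#' Synthetic ABR generator configuration
#'
#' The generator emulates the canonical morphology of a rodent ABR: five
#' positive waves within the first ~6 ms of a 10-ms window, each followed by
#' a negative trough, with peak amplitudes growing and latencies shortening
#' as stimulus level rises above the hearing threshold, and pure recording
#' noise below threshold. Defaults reflect typical mouse ABR values: Wave 1
#' near 1.5 ms, ~5 dB stimulus steps, wave amplitudes of a few microvolts at
#' high sensation levels, and tens-of-nanovolt noise after averaging.
#'
#' @param frequencies Stimulus frequencies, kHz.
#' @param db_levels Stimulus levels, dB SPL (default 0-95 in 5 dB steps).
#' @param base_latencies Wave 1-5 peak latencies (ms) at threshold.
#' @param latency_shift_per_db Latency decrease per dB above threshold
#'   (ms/dB, positive number; default 0.008).
#' @param amplitude_gain_per_db Wave 1 amplitude growth per dB above
#'   threshold (microvolts/dB; default 0.15). At level `d >= threshold` the
#'   nominal Wave 1 bump height is `gain * (d - threshold + step)` where
#'   `step` is the dB spacing.
#' @param wave_rel_amp Relative bump heights of Waves 1-5.
#' @param trough_frac Trough depth as a fraction of its wave's bump height.
#' @param trough_delay Peak-to-trough delay, ms.
#' @param bump_width Gaussian bump width (sd), ms.
#' @param noise_sd Additive Gaussian recording noise, microvolts.
#' @param n_samples,duration Grid settings (canonical 244 samples / 10 ms).
#' @param threshold_range Range (dB) from which per-(subject, frequency)
#'   thresholds are drawn by [synth_corpus()], snapped to the dB step.
#' @return A list of class `abr_synth_config`.
#' @export
synth_config <- function(frequencies = c(12, 24),
                         db_levels = seq(0, 95, by = 5),
                         base_latencies = c(1.5, 2.5, 3.4, 4.4, 5.5),
                         latency_shift_per_db = 0.008,
                         amplitude_gain_per_db = 0.15,
                         wave_rel_amp = c(1, 0.85, 0.6, 0.7, 0.5),
                         trough_frac = 0.6,
                         trough_delay = 0.35,
                         bump_width = 0.15,
                         noise_sd = 0.1,
                         n_samples = 244L,
                         duration = 10,
                         threshold_range = c(20, 60)) {
  stopifnot(all(base_latencies > 0), all(base_latencies < duration),
            noise_sd >= 0, length(wave_rel_amp) == length(base_latencies))
  db_levels <- sort(unique(as.numeric(db_levels)))
  step <- if (length(db_levels) > 1) min(diff(db_levels)) else 5
  if (step > 20) stop("dB step must be <= 20 dB for threshold estimation validity")
  structure(list(frequencies = as.numeric(frequencies), db_levels = db_levels,
                 db_step = step, base_latencies = base_latencies,
                 latency_shift_per_db = latency_shift_per_db,
                 amplitude_gain_per_db = amplitude_gain_per_db,
                 wave_rel_amp = wave_rel_amp, trough_frac = trough_frac,
                 trough_delay = trough_delay, bump_width = bump_width,
                 noise_sd = noise_sd, n_samples = as.integer(n_samples),
                 duration = duration, threshold_range = threshold_range),
            class = "abr_synth_config")
}

# Noiseless trace and its exact grid extrema. Truth is recorded from the
# pre-noise trace: each wave's true peak (trough) is the grid argmax
# (argmin) of the clean trace near the nominal bump (trough) centre, so
# "recover the truth" is well defined down to the sample.
synth_clean <- function(db, threshold, cfg) {
  dt <- cfg$duration / cfg$n_samples
  tt <- (seq_len(cfg$n_samples) - 1) * dt
  v <- numeric(cfg$n_samples)
  truth <- NULL
  if (is.finite(threshold) && db >= threshold) {
    sl <- db - threshold
    a1 <- cfg$amplitude_gain_per_db * (sl + cfg$db_step)
    lat <- cfg$base_latencies - cfg$latency_shift_per_db * sl
    nw <- length(lat)
    for (k in seq_len(nw)) {
      a <- cfg$wave_rel_amp[k] * a1
      v <- v + a * exp(-0.5 * ((tt - lat[k]) / cfg$bump_width)^2)
      v <- v - cfg$trough_frac * a *
        exp(-0.5 * ((tt - (lat[k] + cfg$trough_delay)) / cfg$bump_width)^2)
    }
    half <- min(diff(cfg$base_latencies)) / 2
    pk_i <- tr_i <- integer(nw)
    for (k in seq_len(nw)) {
      win <- which(tt >= lat[k] - half & tt <= lat[k] + half)
      pk_i[k] <- win[which.max(v[win])]
      twin <- which(tt > tt[pk_i[k]] & tt <= lat[k] + cfg$trough_delay + half)
      tr_i[k] <- twin[which.min(v[twin])]
    }
    truth <- data.frame(
      wave = seq_len(nw),
      peak_latency = tt[pk_i], peak_voltage = v[pk_i],
      trough_latency = tt[tr_i], trough_voltage = v[tr_i],
      amplitude = v[pk_i] - v[tr_i]
    )
  }
  list(voltages = v, truth = truth, times = tt)
}

#' Generate one synthetic waveform with ground truth
#'
#' Below threshold the trace is pure Gaussian noise; at or above threshold it
#' is the five-bump clean trace plus noise. Ground truth (exact grid peak and
#' trough latencies and voltages of the clean trace, and the above/below
#' label) is recorded before noise is added. Uses the current RNG state
#' unless `seed` is given.
#'
#' @param subject_id,frequency,db Waveform identity.
#' @param threshold True hearing threshold for this (subject, frequency), dB
#'   SPL; `Inf` for a non-responsive ear.
#' @param cfg A [synth_config()].
#' @param seed Optional integer seed for this one waveform.
#' @return List with `waveform` (an [abr_waveform()]) and `truth` (list:
#'   `waves` data.frame or `NULL`, `label`, `threshold`).
#' @export
synth_waveform <- function(subject_id, frequency, db, threshold,
                           cfg = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cl <- synth_clean(db, threshold, cfg)
  v <- cl$voltages + stats::rnorm(cfg$n_samples, 0, cfg$noise_sd)
  w <- abr_waveform(v, subject_id, frequency, db, duration = cfg$duration,
                    source = "synthetic")
  list(waveform = w,
       truth = list(waves = cl$truth,
                    label = is.finite(threshold) && db >= threshold,
                    threshold = threshold))
}

#' Generate a synthetic ABR series
#'
#' One waveform per level in `cfg$db_levels`, sharing a true threshold.
#'
#' @inheritParams synth_waveform
#' @param seed Integer seed (series-level; generation is bit-reproducible).
#' @return List with `series` (an [abr_series()]) and `truth` (list of
#'   per-waveform truth lists, in ascending dB order, plus `threshold`).
#' @export
synth_series <- function(subject_id, frequency, threshold,
                         cfg = synth_config(), seed = 1L) {
  set.seed(seed)
  gen <- lapply(cfg$db_levels, function(db)
    synth_waveform(subject_id, frequency, db, threshold, cfg))
  list(series = abr_series(lapply(gen, `[[`, "waveform")),
       truth = list(waves = lapply(gen, function(g) g$truth),
                    threshold = threshold))
}

#' Generate a synthetic corpus
#'
#' Draws one true threshold per (subject, frequency) uniformly from
#' `cfg$threshold_range` (snapped to the dB step) and generates the full
#' stimulus series for each. The result is the substrate for training and
#' evaluating every estimator in the package.
#'
#' @param n_subjects Number of subjects.
#' @param cfg A [synth_config()].
#' @param seed Integer seed; the corpus is bit-reproducible.
#' @return List of class `abr_synth_corpus`: `series` (list of
#'   [abr_series()]), `truths` (list of per-series truth lists, parallel to
#'   `series`), and `thresholds` (data.frame subject_id, frequency_khz,
#'   threshold_db).
#' @export
synth_corpus <- function(n_subjects, cfg = synth_config(), seed = 1L) {
  set.seed(seed)
  series <- list()
  truths <- list()
  thr_rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("m%02d", s)
    for (f in cfg$frequencies) {
      steps <- seq(cfg$threshold_range[1], cfg$threshold_range[2], by = cfg$db_step)
      thr <- steps[sample.int(length(steps), 1L)]
      gen <- lapply(cfg$db_levels, function(db)
        synth_waveform(sid, f, db, thr, cfg))
      series[[length(series) + 1L]] <- abr_series(lapply(gen, `[[`, "waveform"))
      truths[[length(truths) + 1L]] <- list(waves = lapply(gen, function(g) g$truth),
                                            threshold = thr)
      thr_rows[[length(thr_rows) + 1L]] <- data.frame(
        subject_id = sid, frequency_khz = f, threshold_db = thr)
    }
  }
  structure(list(series = series, truths = truths,
                 thresholds = do.call(rbind, thr_rows), config = cfg),
            class = "abr_synth_corpus")
}

#' @export
print.abr_synth_corpus <- function(x, ...) {
  cat(sprintf("<abr_synth_corpus> %d series, %d waveforms, thresholds %g..%g dB\n",
              length(x$series), sum(vapply(x$series, length, integer(1))),
              min(x$thresholds$threshold_db), max(x$thresholds$threshold_db)))
  invisible(x)
}

#' Flatten a corpus
#'
#' @param corpus An `abr_synth_corpus`.
#' @return List with parallel vectors/lists: `waveforms`, `label` (above
#'   threshold?), `threshold`, `tau` (true Wave 1 latency, `NA` below
#'   threshold), `amp1` (true Wave 1 amplitude), `series_index`.
#' @export
corpus_flatten <- function(corpus) {
  wfs <- list(); lab <- logical(0); thr <- tau <- amp <- numeric(0); si <- integer(0)
  for (i in seq_along(corpus$series)) {
    ser <- corpus$series[[i]]
    tr <- corpus$truths[[i]]
    for (j in seq_along(ser$waveforms)) {
      wfs[[length(wfs) + 1L]] <- ser$waveforms[[j]]
      tj <- tr$waves[[j]]
      lab <- c(lab, tj$label)
      thr <- c(thr, tr$threshold)
      tau <- c(tau, if (is.null(tj$waves)) NA_real_ else tj$waves$peak_latency[1])
      amp <- c(amp, if (is.null(tj$waves)) NA_real_ else tj$waves$amplitude[1])
      si <- c(si, i)
    }
  }
  list(waveforms = wfs, label = lab, threshold = thr, tau = tau, amp1 = amp,
       series_index = si)
}

#' Suprathreshold subset of a corpus
#'
#' @param corpus An `abr_synth_corpus`.
#' @param min_sl Minimum sensation level (dB above the true threshold).
#' @return As [corpus_flatten()], restricted to waveforms at
#'   `db >= threshold + min_sl`.
#' @export
corpus_suprathreshold <- function(corpus, min_sl = 0) {
  fl <- corpus_flatten(corpus)
  db <- vapply(fl$waveforms, `[[`, numeric(1), "db_spl")
  keep <- is.finite(fl$threshold) & db >= fl$threshold + min_sl
  list(waveforms = fl$waveforms[keep], label = fl$label[keep],
       threshold = fl$threshold[keep], tau = fl$tau[keep],
       amp1 = fl$amp1[keep], series_index = fl$series_index[keep])
}

#' Write a corpus to canonical CSV files
#'
#' @param corpus An `abr_synth_corpus`.
#' @param dir Output directory (created if needed).
#' @return Paths of the waveform CSV and the truth CSV, invisibly.
#' @export
write_synth_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wf_path <- file.path(dir, "waveforms.csv")
  truth_path <- file.path(dir, "truth.csv")
  fl <- corpus_flatten(corpus)
  write_abr_csv(fl$waveforms, wf_path)
  truth <- data.frame(
    subject_id = vapply(fl$waveforms, `[[`, character(1), "subject_id"),
    frequency_khz = vapply(fl$waveforms, `[[`, numeric(1), "frequency"),
    db_spl = vapply(fl$waveforms, `[[`, numeric(1), "db_spl"),
    label_above = as.integer(fl$label),
    threshold_db = fl$threshold,
    wave1_latency_ms = fl$tau,
    wave1_amplitude_uv = fl$amp1
  )
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(waveforms = wf_path, truth = truth_path))
}
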