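#' Construct an ABR waveform
#'
#' The atomic analysis unit: one averaged auditory brainstem response trace
#' recorded for a (subject, stimulus frequency, stimulus level) condition over
#' a short post-stimulus window.
#'
#' Time convention: the trace is treated as `n` samples of period
#' `duration / n` ms, so sample `i` (0-based) sits at
#' `t0 + i * duration / n` ms. On the canonical 244-sample, 10-ms grid the
#' sample period is 10/244 ~ 0.04098 ms, which makes the default peak-search
#' constants (see [peak_find_config()]) exact integer sample counts.
#'
#' @param voltages Numeric vector of voltages, microvolts. Must be non-empty
#'   and finite.
#' @param subject_id Opaque subject identifier (coerced to character).
#' @param frequency Stimulus frequency in kHz, or the string `"click"` for
#'   click stimuli (stored as the reserved code 0).
#' @param db_spl Stimulus intensity, dB SPL; must lie in \[-10, 120\].
#' @param t0 Time of the first sample, ms after stimulus onset. Default 0.
#' @param duration Window length in ms. Default 10.
#' @param source Optional provenance string (e.g. source file path).
#' @return An object of class `abr_waveform`: a list with fields
#'   `subject_id`, `frequency`, `db_spl`, `t0`, `duration`, `voltages`,
#'   `source`.
#' @seealso [abr_series()], [abr_times()], [resample_abr()]
#' @export
abr_waveform <- function(voltages, subject_id, frequency, db_spl,
                         t0 = 0, duration = 10, source = NA_character_) {
  voltages <- as.numeric(voltages)
  if (length(voltages) == 0L) stop("'voltages' must be non-empty")
  if (!all(is.finite(voltages))) stop("'voltages' must all be finite")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("'duration' must be a single positive number (ms)")
  frequency <- parse_frequency(frequency)
  db_spl <- as.numeric(db_spl)
  if (!is.finite(db_spl) || db_spl < -10 || db_spl > 120)
    stop("'db_spl' must be a finite value in [-10, 120]")
  structure(list(
    subject_id = as.character(subject_id),
    frequency = frequency,
    db_spl = db_spl,
    t0 = as.numeric(t0),
    duration = duration,
    voltages = voltages,
    source = as.character(source)
  ), class = "abr_waveform")
}

# "click" (any case) maps to the reserved numeric code 0; tonal frequencies
# must be positive.
parse_frequency <- function(frequency) {
  if (is.character(frequency)) {
    if (tolower(frequency) == "click") return(0)
    frequency <- suppressWarnings(as.numeric(frequency))
  }
  frequency <- as.numeric(frequency)
  if (!is.finite(frequency) || frequency < 0)
    stop("'frequency' must be a positive kHz value or \"click\"")
  frequency
}

#' Sample times of a waveform
#'
#' @param w An [abr_waveform()], or an integer sample count.
#' @param t0,duration Used when `w` is a sample count.
#' @return Numeric vector of sample times in ms (`t0 + i * duration / n`,
#'   `i = 0, ..., n-1`).
#' @export
abr_times <- function(w, t0 = 0, duration = 10) {
  if (inherits(w, "abr_waveform")) {
    n <- length(w$voltages)
    t0 <- w$t0
    duration <- w$duration
  } else {
    n <- as.integer(w)
  }
  dt <- duration / n
  t0 + (seq_len(n) - 1) * dt
}

#' @export
print.abr_waveform <- function(x, ...) {
  freq <- if (x$frequency == 0) "click" else paste0(x$frequency, " kHz")
  cat(sprintf("<abr_waveform> subject %s, %s, %g dB SPL: %d samples over %g ms\n",
              x$subject_id, freq, x$db_spl, length(x$voltages), x$duration))
  invisible(x)
}

#' Construct an ABR series
#'
#' All waveforms for one (subject, frequency), ordered by ascending stimulus
#' level. The series is the unit of threshold estimation.
#'
#' @param waveforms List of [abr_waveform()] objects sharing `subject_id` and
#'   `frequency`. Re-ordered by `db_spl`; duplicated levels keep the first
#'   occurrence with a warning.
#' @return An object of class `abr_series` with fields `subject_id`,
#'   `frequency`, `waveforms`.
#' @export
abr_series <- function(waveforms) {
  if (length(waveforms) == 0L) stop("'waveforms' must be non-empty")
  stopifnot(all(vapply(waveforms, inherits, logical(1), "abr_waveform")))
  sid <- unique(vapply(waveforms, `[[`, character(1), "subject_id"))
  frq <- unique(vapply(waveforms, `[[`, numeric(1), "frequency"))
  if (length(sid) != 1L || length(frq) != 1L)
    stop("all waveforms in a series must share subject_id and frequency")
  dbs <- vapply(waveforms, `[[`, numeric(1), "db_spl")
  ord <- order(dbs)
  waveforms <- waveforms[ord]
  dbs <- dbs[ord]
  if (anyDuplicated(dbs)) {
    warning(sprintf("duplicate dB levels for subject %s, %g kHz: keeping first occurrence",
                    sid, frq))
    waveforms <- waveforms[!duplicated(dbs)]
  }
  structure(list(subject_id = sid, frequency = frq, waveforms = waveforms),
            class = "abr_series")
}

#' @export
print.abr_series <- function(x, ...) {
  dbs <- series_dbs(x)
  freq <- if (x$frequency == 0) "click" else paste0(x$frequency, " kHz")
  cat(sprintf("<abr_series> subject %s, %s: %d levels (%g..%g dB SPL)\n",
              x$subject_id, freq, length(dbs), min(dbs), max(dbs)))
  invisible(x)
}

#' @export
length.abr_series <- function(x) length(x$waveforms)

#' Stimulus levels of a series
#' @param series An [abr_series()].
#' @return Numeric vector of dB SPL values, ascending.
#' @export
series_dbs <- function(series) {
  vapply(series$waveforms, `[[`, numeric(1), "db_spl")
}

#' Voltage matrix of a series
#'
#' @param series An [abr_series()] whose waveforms share one grid.
#' @return Numeric matrix, one row per waveform (ascending dB), one column per
#'   sample.
#' @export
series_matrix <- function(series) {
  ns <- vapply(series$waveforms, function(w) length(w$voltages), integer(1))
  if (length(unique(ns)) != 1L)
    stop("waveforms in the series have unequal sample counts; resample first")
  do.call(rbind, lapply(series$waveforms, `[[`, "voltages"))
}

#' Group waveforms into series
#'
#' Partitions a batch of waveforms by (subject, frequency). Within each series
#' waveforms are sorted by ascending dB SPL; duplicated (subject, frequency,
#' dB) combinations keep the first occurrence with a warning.
#'
#' @param waveforms List of [abr_waveform()] objects.
#' @return List of [abr_series()] objects (empty list for empty input), in
#'   order of first appearance.
#' @export
group_series <- function(waveforms) {
  if (length(waveforms) == 0L) return(list())
  keys <- vapply(waveforms, function(w) paste(w$subject_id, w$frequency, sep = "\r"),
                 character(1))
  idx <- split(seq_along(waveforms), factor(keys, levels = unique(keys)))
  unname(lapply(idx, function(i) abr_series(waveforms[i])))
}
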