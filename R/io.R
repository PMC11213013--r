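#' Canonical ABR CSV dialect
#'
#' Describes how a wide-format ABR CSV maps onto waveform fields, so lab
#' exports with different headers can be adapted without rewriting files.
#' The canonical layout has one waveform per row with columns
#' `subject_id, frequency_khz, db_spl, n_samples, duration_ms, v000...v{n-1}`
#' (voltages in microvolts).
#'
#' @param subject_id,frequency,db_spl,n_samples,duration Column names holding
#'   the corresponding metadata.
#' @param voltage_prefix Prefix of the per-sample voltage columns; samples are
#'   taken in the column order in which they appear.
#' @return A list of class `abr_csv_dialect`.
#' @export
abr_csv_dialect <- function(subject_id = "subject_id",
                            frequency = "frequency_khz",
                            db_spl = "db_spl",
                            n_samples = "n_samples",
                            duration = "duration_ms",
                            voltage_prefix = "v") {
  structure(list(subject_id = subject_id, frequency = frequency,
                 db_spl = db_spl, n_samples = n_samples,
                 duration = duration, voltage_prefix = voltage_prefix),
            class = "abr_csv_dialect")
}

#' Read a batch of ABR CSV files
#'
#' Reads one or more wide-format CSV files (see [abr_csv_dialect()]) into a
#' flat list of waveforms, one per (subject, frequency, dB) row. The source
#' file of each waveform is recorded in its `source` field.
#'
#' @param paths Character vector of file paths.
#' @param dialect An [abr_csv_dialect()]; defaults to the canonical layout.
#' @return List of [abr_waveform()] objects.
#' @export
read_abr_csv <- function(paths, dialect = abr_csv_dialect()) {
  stopifnot(inherits(dialect, "abr_csv_dialect"))
  out <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- tryCatch(
      utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e)
        stop("ABR CSV format error in ", path, ": ", conditionMessage(e),
             call. = FALSE))
    if (nrow(df) == 0L || ncol(df) == 0L)
      stop("ABR CSV format error in ", path, ": file has no data rows")
    for (col in c(dialect$subject_id, dialect$frequency, dialect$db_spl)) {
      if (!col %in% names(df))
        stop("ABR CSV format error in ", path, ": missing required column '", col, "'")
    }
    vcols <- grep(paste0("^", dialect$voltage_prefix, "[0-9]+$"), names(df), value = TRUE)
    if (length(vcols) == 0L)
      stop("ABR CSV format error in ", path, ": no voltage columns with prefix '",
           dialect$voltage_prefix, "'")
    vcols <- vcols[order(as.integer(sub(paste0("^", dialect$voltage_prefix), "", vcols)))]
    for (r in seq_len(nrow(df))) {
      v <- suppressWarnings(as.numeric(unlist(df[r, vcols], use.names = FALSE)))
      if (anyNA(v))
        stop("ABR CSV parse error in ", path, ", row ", r,
             ": non-numeric voltage value")
      n <- if (dialect$n_samples %in% names(df)) as.integer(df[r, dialect$n_samples]) else length(v)
      if (!is.na(n) && n < length(v)) v <- v[seq_len(n)]
      dur <- if (dialect$duration %in% names(df)) as.numeric(df[r, dialect$duration]) else 10
      out[[length(out) + 1L]] <- abr_waveform(
        voltages = v,
        subject_id = df[r, dialect$subject_id],
        frequency = df[r, dialect$frequency],
        db_spl = df[r, dialect$db_spl],
        duration = dur,
        source = path
      )
    }
  }
  out
}

#' Write a batch of waveforms to a canonical ABR CSV
#'
#' @param waveforms List of [abr_waveform()] objects with a common sample
#'   count.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abr_csv <- function(waveforms, path) {
  stopifnot(length(waveforms) > 0L)
  ns <- vapply(waveforms, function(w) length(w$voltages), integer(1))
  if (length(unique(ns)) != 1L)
    stop("all waveforms must share a sample count to share one CSV")
  n <- ns[1]
  width <- max(3L, nchar(as.character(n - 1L)))
  vnames <- sprintf(paste0("v%0", width, "d"), seq_len(n) - 1L)
  meta <- data.frame(
    subject_id = vapply(waveforms, `[[`, character(1), "subject_id"),
    frequency_khz = vapply(waveforms, `[[`, numeric(1), "frequency"),
    db_spl = vapply(waveforms, `[[`, numeric(1), "db_spl"),
    n_samples = n,
    duration_ms = vapply(waveforms, `[[`, numeric(1), "duration"),
    stringsAsFactors = FALSE
  )
  volt <- do.call(rbind, lapply(waveforms, `[[`, "voltages"))
  colnames(volt) <- vnames
  df <- cbind(meta, as.data.frame(volt))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a metrics row
#'
#' One output record per waveform: Wave 1-5 latencies/amplitudes plus the
#' series-level threshold estimate.
#'
#' @param w An [abr_waveform()].
#' @param peaks An `abr_peaks` object from [fine_tune_peaks()], or `NULL` if
#'   peak detection failed for this trace.
#' @param threshold_db Numeric threshold (dB SPL) or `NA` for no response.
#' @param threshold_method Method label recorded in the output.
#' @return A one-row `data.frame`.
#' @export
metrics_row <- function(w, peaks = NULL, threshold_db = NA_real_,
                        threshold_method = NA_character_) {
  lat <- amp <- rep(NA_real_, 5)
  if (!is.null(peaks)) {
    lat <- peaks$peak_latency
    amp <- peaks$amplitude
  }
  df <- data.frame(
    file = w$source,
    subject_id = w$subject_id,
    frequency_khz = w$frequency,
    db_spl = w$db_spl,
    wave1_latency_ms = lat[1], wave1_amplitude_uv = amp[1],
    wave2_latency_ms = lat[2], wave2_amplitude_uv = amp[2],
    wave3_latency_ms = lat[3], wave3_amplitude_uv = amp[3],
    wave4_latency_ms = lat[4], wave4_amplitude_uv = amp[4],
    wave5_latency_ms = lat[5], wave5_amplitude_uv = amp[5],
    threshold_db = threshold_db,
    threshold_method = threshold_method,
    stringsAsFactors = FALSE
  )
  df
}

#' Write per-waveform metrics to CSV
#'
#' Thresholds with no detectable response are rendered as the sentinel `"NR"`.
#' Output is deterministic: identical inputs produce byte-identical files.
#'
#' @param rows A `data.frame` of stacked [metrics_row()] records (possibly
#'   zero rows).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- metrics_row(abr_waveform(0, "x", 1, 0))[0, ]
  }
  rows$threshold_db <- ifelse(is.na(rows$threshold_db), "NR",
                              format(rows$threshold_db, trim = TRUE, scientific = FALSE))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write metrics CSV to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a metrics CSV written by [write_metrics_csv()]
#'
#' @param path File path.
#' @return A `data.frame`; `"NR"` thresholds become `NA` with a logical
#'   `no_response` column set.
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("threshold_db" %in% names(df)) {
    nr <- !is.na(df$threshold_db) & df$threshold_db == "NR"
    df$no_response <- nr
    df$threshold_db <- suppressWarnings(as.numeric(df$threshold_db))
  }
  df
}
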