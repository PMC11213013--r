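#' Batch analysis of ABR recordings
#'
#' End-to-end pipeline: read (or accept) waveforms, group them into series,
#' resample to the canonical grid, detect Wave 1-5 peaks, estimate one
#' threshold per series, and assemble a per-waveform metrics table. Files
#' that fail to parse are skipped with a warning; the run fails only when no
#' input can be processed.
#'
#' @param input Character vector of CSV paths, a list of [abr_waveform()]
#'   objects, or a list of [abr_series()].
#' @param method Threshold method: `"unsupervised"` (default) or a trained
#'   `abr_classifier` passed via `classifier`.
#' @param classifier Optional `abr_classifier`; when supplied, `method` is
#'   taken from its kind.
#' @param wave1_model Optional `wave1_cnn` regressor used to seed the peak
#'   search.
#' @param peak_cfg A [peak_find_config()].
#' @param pre_cfg A [preprocess_config()].
#' @param warp Passed to [unsupervised_threshold()].
#' @param seed Seed for the unsupervised clustering.
#' @param out Optional path; when given, the metrics table is written there
#'   with [write_metrics_csv()].
#' @return The metrics `data.frame`, invisibly when `out` is given.
#' @export
analyze_batch <- function(input, method = "unsupervised", classifier = NULL,
                          wave1_model = NULL,
                          peak_cfg = peak_find_config(),
                          pre_cfg = preprocess_config(),
                          warp = TRUE, seed = 0L, out = NULL) {
  series_list <- if (is.character(input)) {
    wfs <- list()
    for (p in input) {
      wfs_p <- tryCatch(read_abr_csv(p), error = function(e) {
        warning("skipping ", p, ": ", conditionMessage(e))
        NULL
      })
      wfs <- c(wfs, wfs_p)
    }
    if (length(wfs) == 0L) stop("no parseable input files")
    group_series(wfs)
  } else if (length(input) > 0 && inherits(input[[1]], "abr_series")) {
    input
  } else {
    group_series(input)
  }
  rows <- list()
  for (ser in series_list) {
    ser$waveforms <- lapply(ser$waveforms, function(w)
      if (length(w$voltages) == pre_cfg$target_samples) w
      else resample_abr(w, pre_cfg))
    thr <- if (!is.null(classifier)) {
      extract_threshold(ser, classifier)
    } else {
      tryCatch(unsupervised_threshold(ser, warp = warp, seed = seed),
               error = function(e) {
                 warning("threshold estimation failed for subject ",
                         ser$subject_id, ": ", conditionMessage(e))
                 NULL
               })
    }
    thr_db <- if (is.null(thr)) NA_real_ else thr$threshold
    thr_m <- if (is.null(thr)) "failed" else thr$method
    for (w in ser$waveforms) {
      pk <- tryCatch(detect_peaks(w, model = wave1_model, cfg = peak_cfg),
                     error = function(e) NULL)
      rows[[length(rows) + 1L]] <- metrics_row(w, pk, thr_db, thr_m)
    }
  }
  metrics <- do.call(rbind, rows)
  if (!is.null(out)) {
    write_metrics_csv(metrics, out)
    return(invisible(metrics))
  }
  metrics
}

#' Stacked-waveform plot of a series
#'
#' Classic ABR stack: one trace per stimulus level, offset vertically in
#' ascending dB, with detected peaks (circles) and troughs (triangles)
#' marked and the estimated threshold level highlighted.
#'
#' @param x An [abr_series()].
#' @param peaks Optional list of `abr_peaks` (one per waveform, `NULL`
#'   entries allowed).
#' @param threshold Optional `abr_threshold` whose level is highlighted.
#' @param offset Vertical spacing between traces (microvolts); default
#'   chosen from the data.
#' @param ... Passed to [graphics::matplot()].
#' @return The offsets, invisibly.
#' @export
plot.abr_series <- function(x, peaks = NULL, threshold = NULL, offset = NULL,
                            ...) {
  M <- series_matrix(x)
  dbs <- series_dbs(x)
  tt <- abr_times(x$waveforms[[1]])
  if (is.null(offset)) offset <- max(2 * stats::sd(M), 1e-6)
  offs <- (seq_len(nrow(M)) - 1) * offset
  graphics::matplot(tt, t(M + offs), type = "l", lty = 1, col = "grey30",
                    xlab = "time (ms)", ylab = "voltage + offset (µV)",
                    main = sprintf("subject %s, %s", x$subject_id,
                                   if (x$frequency == 0) "click"
                                   else paste0(x$frequency, " kHz")),
                    ...)
  graphics::axis(4, at = offs, labels = dbs, las = 1, cex.axis = 0.6)
  if (!is.null(peaks)) {
    for (i in seq_along(peaks)) {
      pk <- peaks[[i]]
      if (is.null(pk)) next
      ok <- !is.na(pk$peak_latency)
      graphics::points(pk$peak_latency[ok], pk$peak_voltage[ok] + offs[i],
                       col = "red", pch = 19, cex = 0.6)
      ok <- !is.na(pk$trough_latency)
      graphics::points(pk$trough_latency[ok], pk$trough_voltage[ok] + offs[i],
                       col = "blue", pch = 17, cex = 0.6)
    }
  }
  if (!is.null(threshold) && !threshold$no_response) {
    i <- which(dbs == threshold$threshold)
    if (length(i)) graphics::abline(h = offs[i], col = "orange", lty = 2)
  }
  invisible(offs)
}

#' Export a series plot to a file
#'
#' @param series An [abr_series()].
#' @param path Output image path (`.png`).
#' @param ... Passed to [plot.abr_series()].
#' @return `path`, invisibly.
#' @export
plot_series_file <- function(series, path, ...) {
  grDevices::png(path, width = 800, height = 1000, res = 120)
  on.exit(grDevices::dev.off())
  plot(series, ...)
  invisible(path)
}
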