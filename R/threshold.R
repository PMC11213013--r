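#' Threshold result
#'
#' Internal constructor for threshold results. The hearing threshold is the
#' quietest stimulus level (dB SPL) judged to evoke a response; `NA` encodes
#' the no-response sentinel (rendered `"NR"` in CSV output).
#'
#' @param threshold Numeric dB SPL or `NA` (no response).
#' @param calls Integer vector of per-level calls (1 = response), named by
#'   dB.
#' @param method Method label.
#' @param dbs Tested levels, ascending.
#' @return An object of class `abr_threshold`: fields `threshold`, `calls`,
#'   `method`, `step_size`, `step_valid` (TRUE when the maximum step is
#'   <= 20 dB, the regime where level-by-level thresholding is meaningful),
#'   `no_response`.
#' @keywords internal
new_abr_threshold <- function(threshold, calls, method, dbs) {
  step <- if (length(dbs) > 1) max(diff(sort(dbs))) else NA_real_
  structure(list(threshold = threshold,
                 calls = calls,
                 method = method,
                 step_size = step,
                 step_valid = is.na(step) || step <= 20,
                 no_response = is.na(threshold)),
            class = "abr_threshold")
}

#' @export
print.abr_threshold <- function(x, ...) {
  thr <- if (x$no_response) "NR (no response)" else sprintf("%g dB SPL", x$threshold)
  cat(sprintf("<abr_threshold> %s [method: %s, step %g dB]\n",
              thr, x$method, x$step_size))
  cat("calls:", paste(sprintf("%s:%d", names(x$calls), x$calls), collapse = " "), "\n")
  invisible(x)
}

#' Threshold from per-level response calls
#'
#' Applies the threshold rule to a set of binary per-level calls.
#' `monotone_closure` (default): the threshold is the lowest level d such
#' that the call at d and at every tested level above d is positive - a
#' deterministic, conservative reading when calls are non-monotone. All
#' calls negative gives the no-response sentinel; all positive gives the
#' lowest tested level. `first_positive`: the lowest level with a positive
#' call.
#'
#' @param dbs Tested levels (dB SPL).
#' @param calls Binary calls (1 = response), parallel to `dbs`.
#' @param rule `"monotone_closure"` or `"first_positive"`.
#' @param method Method label stored in the result.
#' @return An `abr_threshold` object.
#' @export
extract_threshold_calls <- function(dbs, calls,
                                    rule = c("monotone_closure", "first_positive"),
                                    method = "manual") {
  rule <- match.arg(rule)
  ord <- order(dbs)
  dbs <- dbs[ord]
  calls <- as.integer(calls[ord] != 0)
  named <- stats::setNames(calls, dbs)
  thr <- if (rule == "monotone_closure") {
    closed <- rev(cumprod(rev(calls)))
    if (all(closed == 0)) NA_real_ else dbs[which(closed == 1)[1]]
  } else {
    if (all(calls == 0)) NA_real_ else dbs[which(calls == 1)[1]]
  }
  new_abr_threshold(thr, named, method, dbs)
}

#' Threshold of a series under a trained classifier
#'
#' Classifies every waveform of the series and applies the threshold rule to
#' the calls (probability >= 0.5).
#'
#' @param series An [abr_series()].
#' @param model An `abr_classifier` from [train_abr_classifier()].
#' @param rule See [extract_threshold_calls()].
#' @return An `abr_threshold` object.
#' @export
extract_threshold <- function(series, model,
                              rule = c("monotone_closure", "first_positive")) {
  stopifnot(inherits(series, "abr_series"))
  rule <- match.arg(rule)
  p <- classify(model, series)
  extract_threshold_calls(series_dbs(series), as.integer(p >= 0.5),
                          rule = rule, method = model$kind)
}

#' Agreement between estimated and true thresholds
#'
#' Fraction of series whose estimate falls within each dB envelope of the
#' truth. A no-response estimate matching a no-response truth counts as
#' agreement at every envelope; no-response against a numeric threshold
#' counts as disagreement at every envelope.
#'
#' @param est Numeric vector of estimated thresholds (`NA` = no response).
#' @param truth Numeric vector of true thresholds (`NA` = no response).
#' @param envelopes dB envelopes (default 5, 10, 15).
#' @return Named numeric vector of agreement fractions.
#' @export
threshold_agreement <- function(est, truth, envelopes = c(5, 10, 15)) {
  stopifnot(length(est) == length(truth))
  out <- vapply(envelopes, function(e) {
    ok <- (is.na(est) & is.na(truth)) |
      (!is.na(est) & !is.na(truth) & abs(est - truth) <= e)
    mean(ok)
  }, numeric(1))
  stats::setNames(out, paste0("within_", envelopes, "dB"))
}
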