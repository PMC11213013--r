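test_that("search constants snap to whole samples on the canonical grid", {
  dt <- 10 / 244
  cfg <- peak_find_config()
  expect_identical(round(cfg$search_back_window / dt), 9)
  expect_identical(round(cfg$min_peak_separation / dt), 18)
  expect_identical(round(cfg$min_trough_separation / dt), 14)
})

test_that("a single bump is localized from a biased seed estimate", {
  v <- 2 * gauss_bump(2.00, width = 0.3)
  w <- make_waveform(v)
  pk <- fine_tune_peaks(w, t_hat = 2.20)
  # oracle: exhaustive argmax over the search range
  expect_lt(abs(pk$peak_latency[1] - 2.00), 10 / 244 + 1e-12)
  expect_identical(pk$peak_index[1],
                   which.max(smooth_abr(v, 1.0)))
})

test_that("flat and empty-search traces raise the no-peak condition", {
  w <- make_waveform(numeric(244))
  expect_error(fine_tune_peaks(w, 2.0), class = "abr_no_peak")
  expect_error(fine_tune_peaks(make_waveform(rnorm(244)), t_hat = 99),
               "window")
})

test_that("five bumps yield five interleaved peak/trough pairs at the bump centres", {
  tr <- five_bump_trace(first = 1.5, spacing = 1.0)
  w <- make_waveform(tr$voltages)
  pk <- fine_tune_peaks(w, t_hat = tr$centers[1])
  expect_false(anyNA(pk$peak_latency))
  expect_true(all(abs(pk$peak_latency - tr$centers) <= 10 / 244 + 1e-12))
  expect_true(all(diff(pk$peak_latency) > 0))
  ok <- !is.na(pk$trough_latency)
  expect_true(all(pk$trough_latency[ok] > pk$peak_latency[ok]))
  expect_true(pk$validated[1])
  expect_false(any(pk$validated[-1]))
})

test_that("refinement agrees exactly with the exhaustive constrained oracle", {
  set.seed(42)
  n_checked <- 0
  for (i in 1:120) {
    v <- random_trace()
    t_hat <- runif(1, 0.5, 9.5)
    w <- make_waveform(v)
    imp <- tryCatch(fine_tune_peaks(w, t_hat), error = function(e) NULL)
    ora <- oracle_peakset(v, t_hat)
    expect_identical(is.null(imp), is.null(ora))
    if (is.null(imp)) next
    expect_identical(as.integer(imp$peak_index), as.integer(ora$peaks))
    expect_identical(as.integer(imp$trough_index), as.integer(ora$troughs))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
})

test_that("reported voltages always come from the unsmoothed trace", {
  set.seed(9)
  for (i in 1:25) {
    v <- random_trace()
    w <- make_waveform(v)
    pk <- tryCatch(fine_tune_peaks(w, 5), error = function(e) NULL)
    if (is.null(pk)) next
    ok <- !is.na(pk$peak_index)
    expect_identical(pk$peak_voltage[ok], v[pk$peak_index[ok]])
    ok <- !is.na(pk$trough_index)
    expect_identical(pk$trough_voltage[ok], v[pk$trough_index[ok]])
  }
})

test_that("peak latencies are strictly increasing in every returned set", {
  set.seed(13)
  for (i in 1:50) {
    w <- make_waveform(random_trace())
    pk <- tryCatch(fine_tune_peaks(w, runif(1, 1, 6)),
                   error = function(e) NULL)
    if (is.null(pk)) next
    lat <- pk$peak_latency[!is.na(pk$peak_latency)]
    if (length(lat) > 1) expect_true(all(diff(lat) > 0))
  }
})

test_that("amplitude conventions are applied as configured", {
  tr <- five_bump_trace()
  w <- make_waveform(tr$voltages)
  p2t <- fine_tune_peaks(w, tr$centers[1], peak_find_config())
  pabs <- fine_tune_peaks(w, tr$centers[1],
                          peak_find_config(amplitude_mode = "peak_absolute"))
  expect_equal(p2t$amplitude[1], p2t$peak_voltage[1] - p2t$trough_voltage[1])
  expect_equal(pabs$amplitude[1], pabs$peak_voltage[1])
})

test_that("detection is deterministic and composes the two steps", {
  tr <- five_bump_trace()
  w <- make_waveform(tr$voltages)
  a <- detect_peaks(w)
  b <- detect_peaks(w)
  expect_identical(a, b)
  expect_false(anyNA(a$peak_latency))
})

test_that("signed errors follow their definitions and summarize correctly", {
  pk <- list(peak_latency = c(2.05, NA, NA, NA, NA),
             amplitude = c(1.5, NA, NA, NA, NA))
  err <- compute_errors(pk, tau_true = 2.00, a_true = 1.5)
  expect_equal(err$e_tau, 0.05)
  expect_equal(err$e_a, 0)
  expect_error(compute_errors(list(peak_latency = NA_real_,
                                   amplitude = NA_real_), 2.0),
               "undefined")
  # 3-record arithmetic oracle
  recs <- list(list(e_tau = 0.1, e_a = 0.2),
               list(e_tau = -0.1, e_a = 0.1),
               list(e_tau = 0.3, e_a = -0.3))
  sm <- summarize_errors(recs)
  expect_equal(sm$mean[sm$metric == "e_tau"], 0.1)
  expect_equal(sm$se[sm$metric == "e_tau"], 0.2 / sqrt(3))
  expect_equal(sm$mean[sm$metric == "e_a"], 0)
})
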