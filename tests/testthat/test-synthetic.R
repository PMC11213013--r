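test_that("corpus dimensions and labels are consistent with the thresholds", {
  cfg <- synth_config()
  corp <- synth_corpus(5, cfg, seed = 1)
  expect_length(corp$series, 10L)                 # 5 subjects x 2 frequencies
  fl <- corpus_flatten(corp)
  expect_length(fl$waveforms, 200L)               # x 20 levels
  db <- vapply(fl$waveforms, `[[`, numeric(1), "db_spl")
  expect_identical(fl$label, db >= fl$threshold)
  expect_true(all(corp$thresholds$threshold_db >= 20 &
                    corp$thresholds$threshold_db <= 60))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- synth_corpus(2, synth_config(), seed = 9)
  b <- synth_corpus(2, synth_config(), seed = 9)
  expect_identical(a, b)
  c2 <- synth_corpus(2, synth_config(), seed = 10)
  expect_false(identical(a$series, c2$series))
})

test_that("subthreshold traces are pure noise at the configured scale", {
  cfg <- synth_config(noise_sd = 0.1)
  g <- synth_waveform("m1", 12, db = 20, threshold = 60, cfg, seed = 4)
  expect_null(g$truth$waves)
  expect_false(g$truth$label)
  expect_lt(max(abs(g$waveform$voltages)), 0.1 * 5)
  expect_gt(stats::sd(g$waveform$voltages), 0.05)
})

test_that("noiseless traces yield exact recovery of all five true latencies", {
  cfg <- synth_config(noise_sd = 0)
  g <- synth_waveform("m1", 12, db = 80, threshold = 40, cfg, seed = 1)
  truth <- g$truth$waves
  pk <- fine_tune_peaks(g$waveform, t_hat = truth$peak_latency[1])
  expect_identical(pk$peak_latency, truth$peak_latency)
  expect_identical(pk$trough_latency, truth$trough_latency)
  expect_equal(pk$amplitude, truth$amplitude)
})

test_that("true amplitude grows and latency shrinks with stimulus level", {
  cfg <- synth_config(noise_sd = 0)
  ss <- synth_series("m1", 12, threshold = 30, cfg, seed = 1)
  above <- Filter(function(x) !is.null(x$waves), ss$truth$waves)
  amp <- vapply(above, function(x) x$waves$amplitude[1], numeric(1))
  lat <- vapply(above, function(x) x$waves$peak_latency[1], numeric(1))
  expect_true(all(diff(amp) > 0))
  expect_true(all(diff(lat) <= 0))
  expect_lt(sum(diff(lat) == 0), length(lat) / 3)   # grid ties only
})

test_that("a generated corpus round-trips through the CSV layer", {
  corp <- synth_corpus(2, synth_config(db_levels = seq(20, 60, 10)), seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_synth_corpus(corp, dir)
  expect_true(all(file.exists(paths)))
  back <- read_abr_csv(paths[["waveforms"]])
  fl <- corpus_flatten(corp)
  expect_length(back, length(fl$waveforms))
  i <- 7
  expect_equal(back[[i]]$voltages, fl$waveforms[[i]]$voltages,
               tolerance = 1e-9)
  expect_identical(back[[i]]$db_spl, fl$waveforms[[i]]$db_spl)
})
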