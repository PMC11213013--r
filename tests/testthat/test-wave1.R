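test_that("constant-target regression recovers the constant", {
  set.seed(2)
  wfs <- lapply(1:60, function(i)
    make_waveform(2 * gauss_bump(2.0, 0.3) + rnorm(244, 0, 0.05)))
  m <- train_wave1_cnn(wfs[1:40], rep(2.0, 40), epochs = 15, seed = 1)
  pred <- predict(m, wfs[41:60])
  expect_true(all(abs(pred - 2.0) < 0.05))
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(4)
  wfs <- lapply(1:30, function(i)
    make_waveform(gauss_bump(runif(1, 1.2, 1.8), 0.3) + rnorm(244, 0, 0.05)))
  tau <- runif(30, 1.2, 1.8)
  m1 <- train_wave1_cnn(wfs, tau, epochs = 3, seed = 7)
  m2 <- train_wave1_cnn(wfs, tau, epochs = 3, seed = 7)
  expect_identical(predict(m1, wfs), predict(m2, wfs))
})

test_that("tiny training sets and bad labels are rejected", {
  wfs <- lapply(1:5, function(i) make_waveform(rnorm(244)))
  expect_error(train_wave1_cnn(wfs, rep(2, 5)), "insufficient")
  wfs <- lapply(1:25, function(i) make_waveform(rnorm(244)))
  expect_error(train_wave1_cnn(wfs, rep(12, 25)), "window")
})

test_that("the regressor learns latency structure on a small synthetic set", {
  cfg <- synth_config(frequencies = 12)
  corp <- synth_corpus(12, cfg, seed = 5)
  sup <- corpus_suprathreshold(corp, min_sl = 5)
  sid <- vapply(sup$waveforms, `[[`, character(1), "subject_id")
  te <- sid %in% tail(unique(sid), 3)
  m <- train_wave1_cnn(sup$waveforms[!te], sup$tau[!te],
                       epochs = 25, seed = 1)
  mae <- mean(abs(predict(m, sup$waveforms[te]) - sup$tau[te]))
  expect_lt(mae, 0.15)
})

test_that("models survive a text save/load round trip", {
  set.seed(6)
  wfs <- lapply(1:25, function(i)
    make_waveform(gauss_bump(1.5, 0.3) + rnorm(244, 0, 0.05)))
  m <- train_wave1_cnn(wfs, rep(1.5, 25), epochs = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".txt")
  save_abr_model(m, path)
  m2 <- load_abr_model(path)
  expect_s3_class(m2, "wave1_cnn")
  expect_equal(predict(m2, wfs), predict(m, wfs), tolerance = 1e-12)
})
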