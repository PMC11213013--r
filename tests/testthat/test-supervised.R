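test_that("grouped split allocates whole groups with no leakage", {
  wfs <- list()
  for (s in 1:5) for (f in c(12, 24))
    for (d in c(20, 40)) wfs[[length(wfs) + 1L]] <-
      abr_waveform(rnorm(50), paste0("m", s), f, d)
  sp <- grouped_split(wfs, 0.8, seed = 1)     # 10 groups -> 8/2
  expect_identical(length(unique(sp$groups[sp$train])), 8L)
  expect_identical(length(unique(sp$groups[sp$test])), 2L)
  expect_length(intersect(sp$groups[sp$train], sp$groups[sp$test]), 0L)
  sp2 <- grouped_split(wfs, 0.8, seed = 1)
  expect_identical(sp, sp2)
  for (seed in 2:6) {
    spx <- grouped_split(wfs, 0.8, seed = seed)
    expect_length(intersect(spx$groups[spx$train], spx$groups[spx$test]), 0L)
  }
  expect_error(grouped_split(wfs[1:2], 0.8), "2 .*groups")
})

test_that("a linearly separable toy set is fit perfectly by logistic regression", {
  set.seed(17)
  base <- gauss_bump(3, 0.5)
  wfs <- c(lapply(1:20, function(i) make_waveform(base + rnorm(244, 0, 0.1))),
           lapply(1:20, function(i) make_waveform(base + 5 + rnorm(244, 0, 0.1))))
  labels <- rep(c(0, 1), each = 20)
  m <- train_abr_classifier("logistic", wfs, labels, warp = FALSE, seed = 1)
  p <- predict(m, abr_feature_matrix(wfs))
  expect_identical(as.integer(p >= 0.5), as.integer(labels))
})

test_that("single-class training sets are rejected", {
  wfs <- lapply(1:10, function(i) make_waveform(rnorm(244)))
  expect_error(train_abr_classifier("logistic", wfs, rep(1, 10)),
               "degenerate")
})

test_that("probabilities are bounded, deterministic, and shape-checked", {
  set.seed(19)
  wfs <- c(lapply(1:15, function(i) make_waveform(rnorm(244), db = 20)),
           lapply(1:15, function(i)
             make_waveform(3 * gauss_bump(2, 0.3) + rnorm(244), db = 80)))
  m <- train_abr_classifier("xgboost", wfs, rep(c(0, 1), each = 15),
                            warp = FALSE, seed = 1, nrounds = 20)
  X <- abr_feature_matrix(wfs)
  p1 <- predict(m, X); p2 <- predict(m, X)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(predict(m, matrix(0, 2, 10)), "shape")
})

test_that("predicted response probability rises with stimulus level", {
  ss <- synth_series("m1", 12, threshold = 40, synth_config(), seed = 2)
  other <- synth_series("m2", 12, threshold = 45, synth_config(), seed = 3)
  fl_w <- c(ss$series$waveforms, other$series$waveforms)
  labs <- c(vapply(ss$truth$waves, `[[`, logical(1), "label"),
            vapply(other$truth$waves, `[[`, logical(1), "label"))
  m <- train_abr_classifier("xgboost", fl_w, labs, warp = FALSE,
                            seed = 1, nrounds = 40)
  p <- predict(m, abr_feature_matrix(ss$series$waveforms))
  expect_gt(cor(series_dbs(ss$series), p, method = "spearman"), 0)
})

test_that("threshold extraction follows the monotone-closure rule", {
  dbs <- seq(20, 90, 5)
  calls <- as.integer(dbs >= 25)
  expect_equal(extract_threshold_calls(dbs, calls)$threshold, 25)
  expect_true(extract_threshold_calls(dbs, rep(0, length(dbs)))$no_response)
  # non-monotone pattern, worked by hand: only 90 has closure
  r <- extract_threshold_calls(c(60, 70, 80, 90), c(0, 1, 0, 1))
  expect_equal(r$threshold, 90)
  r2 <- extract_threshold_calls(c(60, 70, 80, 90), c(0, 1, 0, 1),
                                rule = "first_positive")
  expect_equal(r2$threshold, 70)
  expect_equal(extract_threshold_calls(dbs, rep(1, length(dbs)))$threshold, 20)
})

test_that("the closure rule matches brute force over all call patterns", {
  for (k in c(3, 5, 8)) {
    dbs <- seq(20, by = 5, length.out = k)
    for (code in 0:(2^k - 1)) {
      calls <- as.integer(intToBits(code)[1:k])
      got <- extract_threshold_calls(dbs, calls)$threshold
      want <- oracle_threshold(dbs, calls)
      expect_identical(got, want)
    }
  }
})

test_that("classifier metrics follow their definitions", {
  labels <- rep(c(1, 0), each = 10)
  perfect <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))
  ev <- evaluate_classifier(labels, perfect)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auroc, 1)
  expect_equal(ev$auprc, 1, tolerance = 1e-9)
  # contingency table TP=9 FN=1 FP=1 TN=9
  labels2 <- c(rep(1, 10), rep(0, 10))
  probs2 <- c(rep(0.9, 9), 0.1, 0.9, rep(0.1, 9))
  ev2 <- evaluate_classifier(labels2, probs2)
  expect_equal(ev2$tpr, 0.9)
  expect_equal(ev2$fpr, 0.1)
  expect_error(evaluate_classifier(rep(1, 5), runif(5)), "single class")
})

test_that("threshold agreement counts NR conventions as documented", {
  est <- c(30, 40, NA)
  truth <- c(25, 40, NA)
  ag <- threshold_agreement(est, truth)
  expect_equal(unname(ag["within_5dB"]), 1)
  ag2 <- threshold_agreement(c(30, 40, NA), c(25, 40, 60))
  expect_equal(unname(ag2["within_5dB"]), 2 / 3)
  expect_equal(unname(ag2["within_15dB"]), 2 / 3)
})
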