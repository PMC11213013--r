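test_that("resampling the canonical grid onto itself is the identity", {
  w <- make_waveform(rnorm(244))
  out <- resample_abr(w, preprocess_config(244, 10))
  expect_identical(out$voltages, w$voltages)
})

test_that("resampling is exact on affine signals", {
  tt <- canon_times(488, 10)
  w <- abr_waveform(3 * tt, "m1", 12, 50)
  out <- resample_abr(w, preprocess_config(244, 10))
  expect_equal(out$voltages, 3 * canon_times(244, 10), tolerance = 1e-12)
})

test_that("resampling matches a manual two-point interpolation oracle", {
  n_in <- 100
  t_in <- canon_times(n_in, 10)
  v_in <- sin(2 * pi * 1 * t_in)      # 1 kHz sine over the 10 ms window
  w <- abr_waveform(v_in, "m1", 12, 50)
  out <- resample_abr(w, preprocess_config(244, 10))
  t_out <- canon_times(244, 10)
  manual <- vapply(t_out, function(t) {
    if (t >= t_in[n_in]) return(v_in[n_in])   # hold last value on the tail
    j <- findInterval(t, t_in)
    f <- (t - t_in[j]) / (t_in[j + 1] - t_in[j])
    v_in[j] * (1 - f) + v_in[j + 1] * f
  }, numeric(1))
  expect_equal(out$voltages, manual, tolerance = 1e-12)
})

test_that("degenerate and under-covering inputs are rejected", {
  expect_error(resample_abr(abr_waveform(1, "m", 12, 50)), "degenerate")
  short <- abr_waveform(rnorm(100), "m", 12, 50, duration = 5)
  expect_error(resample_abr(short, preprocess_config(244, 10)), "coverage")
})

test_that("smoothing preserves constants and is linear", {
  const <- rep(2.5, 100)
  expect_equal(smooth_abr(const, 1.0), const, tolerance = 1e-9)
  set.seed(3)
  x <- rnorm(150); y <- rnorm(150)
  expect_equal(smooth_abr(x + y, 1.3),
               smooth_abr(x, 1.3) + smooth_abr(y, 1.3), tolerance = 1e-9)
})

test_that("an impulse smooths to the normalized discrete Gaussian kernel", {
  v <- numeric(61); v[31] <- 1
  sm <- smooth_abr(v, 1.0)
  r <- ceiling(4 * 1.0)
  k <- exp(-0.5 * ((-r:r) / 1.0)^2); k <- k / sum(k)
  expect_equal(sm[(31 - r):(31 + r)], k, tolerance = 1e-12)
  expect_equal(sm[1:(30 - r)], numeric(30 - r))
})

test_that("smoothing matches the explicit kernel oracle on random traces", {
  set.seed(11)
  for (i in 1:5) {
    v <- random_trace(80)
    sigma <- runif(1, 0.5, 2)
    expect_equal(smooth_abr(v, sigma), oracle_smooth(v, sigma),
                 tolerance = 1e-12)
  }
})

test_that("smoothing preserves the mean of interior-supported signals", {
  set.seed(5)
  v <- numeric(244)
  v[30:210] <- rnorm(181)
  expect_lt(abs(mean(smooth_abr(v, 1.0)) - mean(v)), 1e-6)
})

test_that("smoothing never increases the number of strict local maxima", {
  set.seed(7)
  n_max <- function(v) length(oracle_prune(v, 1))
  for (i in 1:200) {
    v <- random_trace(122)
    expect_lte(n_max(smooth_abr(v, 1.0)), n_max(v))
  }
})
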