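test_that("self-alignment returns identity warps", {
  v <- 2 * gauss_bump(3.0, 0.3)
  wr <- align_series(rbind(v, v))
  expect_lt(max(abs(sweep(wr$warps, 2, wr$times))), 1e-3)
  expect_equal(wr$aligned[1, ], wr$aligned[2, ])
})

test_that("oppositely shifted bumps register to a common peak", {
  M <- rbind(2 * gauss_bump(3.0 - 0.4, 0.3), 2 * gauss_bump(3.0 + 0.4, 0.3))
  before <- apply(M, 1, which.max)
  wr <- align_series(M)
  after <- apply(wr$aligned, 1, which.max)
  expect_gt(abs(diff(before)), 15)
  expect_lte(abs(diff(after)), 1)
})

test_that("all warps are monotone and endpoint-fixed", {
  set.seed(21)
  M <- do.call(rbind, lapply(1:6, function(i) random_trace()))
  wr <- align_series(M)
  for (i in 1:6) {
    g <- wr$warps[i, ]
    expect_true(all(diff(g) > 0))
    expect_equal(g[1], 0, tolerance = 1e-6)
    expect_equal(g[length(g)], wr$times[length(wr$times)], tolerance = 1e-6)
  }
})

test_that("constant series fall back to identity warps with a warning", {
  M <- rbind(rep(1, 100), rep(2, 100))
  expect_warning(wr <- align_series(M), "constant")
  expect_equal(wr$warps[1, ], wr$times)
})

test_that("alignment reduces cross-sectional Wave 1 latency variance", {
  set.seed(31)
  jit <- seq(-0.3, 0.3, length.out = 8)       # jitter spread >= 0.2 ms
  M <- do.call(rbind, lapply(jit, function(j)
    five_bump_trace(first = 1.5 + j)$voltages + rnorm(244, 0, 0.05)))
  tt <- canon_times()
  # latency of the Wave 1 peak: argmax near the first bump of the template
  wr <- align_series(M)
  tw1 <- tt[which.max(wr$template * (tt < 3))]
  lat <- function(X) apply(X, 1, function(v)
    tt[which.max(v * (tt > tw1 - 0.5 & tt < tw1 + 0.5))])
  expect_lt(var(lat(wr$aligned)), var(lat(M)))
})

test_that("warping preserves each curve's value range (amplitude/phase decoupling)", {
  set.seed(41)
  M <- do.call(rbind, lapply(1:5, function(i)
    five_bump_trace(first = 1.4 + 0.1 * i)$voltages))
  wr <- align_series(M)
  for (i in 1:5) {
    expect_lte(max(wr$aligned[i, ]), max(M[i, ]) + 1e-9)
    expect_gte(min(wr$aligned[i, ]), min(M[i, ]) - 1e-9)
  }
})

test_that("warp features subsample the warps monotonically", {
  v <- gauss_bump(3, 0.3)
  wr <- align_series(rbind(v, v))
  wf <- warp_features(wr, 5)
  expect_equal(wf[1, ], c(0, 2.5, 5, 7.5, 10))
  M <- rbind(gauss_bump(2.6, 0.3), gauss_bump(3.4, 0.3))
  wf2 <- warp_features(align_series(M), 11)
  expect_true(all(apply(wf2, 1, function(g) all(diff(g) >= 0))))
  # displacement ordering shows up mid-window
  expect_lt(wf2[1, 6], wf2[2, 6])
})
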