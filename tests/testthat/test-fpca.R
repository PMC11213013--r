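test_that("a rank-2 curve family is fully captured by two components", {
  set.seed(8)
  tt <- canon_times(60, 10)
  f <- sin(2 * pi * tt / 10); g <- cos(2 * pi * tt / 10)
  M <- do.call(rbind, lapply(1:10, function(i)
    rnorm(1, 0, 2) * f + rnorm(1, 0, 1) * g))
  fp <- abr_fpca(M, 2)
  expect_equal(sum(fp$variance_explained), 1, tolerance = 1e-9)
  expect_lt(sum(fp$eigenvalues[-(1:2)]), 1e-18)
})

test_that("identical curves give a degenerate zero-score decomposition", {
  M <- do.call(rbind, lapply(1:5, function(i) gauss_bump(3, 0.3)))
  fp <- abr_fpca(M, 2)
  expect_true(fp$degenerate)
  expect_equal(fp$scores, matrix(0, 5, 2))
})

test_that("eigenvalues and scores match a dense covariance eigensolver", {
  set.seed(12)
  M <- matrix(rnorm(12 * 24), 12, 24)
  fp <- abr_fpca(M, 2)
  # oracle: eigendecomposition of the explicit covariance matrix
  C <- sweep(M, 2, colMeans(M))
  eg <- eigen(stats::cov(M), symmetric = TRUE)
  expect_equal(fp$eigenvalues[1:11], eg$values[1:11], tolerance = 1e-8)
  for (j in 1:2) {
    sc_o <- C %*% eg$vectors[, j]
    # eigenfunctions are sign-fixed; compare up to sign
    s <- sign(sum(sc_o * fp$scores[, j]))
    expect_equal(fp$scores[, j], s * as.numeric(sc_o), tolerance = 1e-8)
  }
})

test_that("scores are invariant under adding a constant curve to all inputs", {
  set.seed(14)
  M <- matrix(rnorm(8 * 40), 8, 40)
  shift <- matrix(rep(sin(seq_len(40) / 5), each = 8), 8, 40)
  a <- abr_fpca(M, 2); b <- abr_fpca(M + shift, 2)
  for (j in 1:2) {
    s <- sign(sum(a$scores[, j] * b$scores[, j]))
    expect_equal(a$scores[, j], s * b$scores[, j], tolerance = 1e-8)
  }
})

test_that("too few curves raise a rank error", {
  expect_error(abr_fpca(matrix(rnorm(2 * 10), 2, 10)), "rank")
})

test_that("two principal components dominate a typical synthetic series", {
  ss <- synth_series("m1", 12, threshold = 25,
                     synth_config(noise_sd = 0.05), seed = 3)
  fp <- abr_fpca(series_matrix(ss$series), 2, warp_first = TRUE)
  expect_gte(sum(fp$variance_explained), 0.95)
})

test_that("separated score clouds split perfectly and label by distance from origin", {
  pts <- rbind(matrix(0, 5, 2), cbind(rep(10, 5), rep(0, 5)))
  ca <- cluster_scores(pts, seed = 0)
  expect_identical(as.character(ca$labels),
                   c(rep("below", 5), rep("above", 5)))
})

test_that("degenerate score sets are labelled below", {
  ca <- cluster_scores(matrix(0, 6, 2), seed = 0)
  expect_true(ca$degenerate)
  expect_true(all(ca$labels == "below"))
  expect_error(cluster_scores(matrix(0, 1, 2)), "at least 2")
})

test_that("a separated 2-D Gaussian mixture is recovered with few mistakes", {
  set.seed(3)
  n <- 50
  pts <- rbind(cbind(rnorm(n), rnorm(n)),
               cbind(rnorm(n, 6), rnorm(n)))
  truth <- rep(c("below", "above"), each = n)
  ca <- cluster_scores(pts, seed = 3)
  expect_lte(mean(as.character(ca$labels) != truth), 0.05)
})
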