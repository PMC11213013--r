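# Independent oracles used by the test suite. These re-derive expected
# results by direct exhaustive computation, separately from the package's
# implementation paths.

# Exhaustive constrained extremum scan: strict local maxima of `seg` found
# by direct neighbour comparison, then thinned by repeatedly taking the
# tallest remaining candidate (ties: lowest index) and discarding every
# candidate closer than `min_sep` samples to an already-selected one.
oracle_prune <- function(seg, min_sep, minima = FALSE) {
  v <- if (minima) -seg else seg
  cand <- integer(0)
  for (i in seq_along(v)) {
    if (i > 1 && i < length(v) && v[i] > v[i - 1] && v[i] > v[i + 1])
      cand <- c(cand, i)
  }
  sel <- integer(0)
  while (length(cand) > 0) {
    h <- v[cand]
    best <- cand[h == max(h)]
    best <- min(best)
    sel <- c(sel, best)
    cand <- cand[abs(cand - best) >= min_sep]
  }
  sort(sel)
}

# Full oracle for the two-step refinement: same contract as
# fine_tune_peaks(), evaluated by the exhaustive scan above. Returns
# 1-based peak/trough indices into the full trace, or NULL when no peak
# exists in the search range.
oracle_peakset <- function(voltages, t_hat, duration = 10,
                           sigma = 1.0, back_ms = 0.3689,
                           sep_p_ms = 0.7377, sep_t_ms = 0.5738,
                           n_waves = 5) {
  n <- length(voltages)
  dt <- duration / n
  sm <- smooth_abr(voltages, sigma)
  start <- min(max(1L, 1L + as.integer(round(t_hat / dt)) -
                     max(1L, as.integer(round(back_ms / dt)))), n)
  seg <- sm[start:n]
  pk <- oracle_prune(seg, max(1L, round(sep_p_ms / dt)))
  if (length(pk) == 0) return(NULL)
  tr <- oracle_prune(seg, max(1L, round(sep_t_ms / dt)), minima = TRUE)
  pk <- pk[seq_len(min(n_waves, length(pk)))]
  peaks <- pk + start - 1L
  troughs <- rep(NA_integer_, n_waves)
  for (k in seq_along(pk)) {
    upper <- if (k < length(pk)) pk[k + 1] else length(seg) + 1L
    inside <- tr[tr > pk[k] & tr < upper]
    if (length(inside)) troughs[k] <- inside[1] + start - 1L
  }
  list(peaks = c(peaks, rep(NA_integer_, n_waves - length(peaks))),
       troughs = troughs)
}

# Direct discrete Gaussian smoothing oracle: explicit kernel formula and
# mirror-extension, evaluated sample by sample.
oracle_smooth <- function(v, sigma) {
  r <- ceiling(4 * sigma)
  w <- exp(-0.5 * ((-r:r) / sigma)^2)
  w <- w / sum(w)
  n <- length(v)
  mirror <- function(i) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in -r:r) s <- s + w[j + r + 1] * v[mirror(i + j)]
    out[i] <- s
  }
  out
}

# Brute-force threshold rule: enumerate levels directly.
oracle_threshold <- function(dbs, calls, rule = "monotone_closure") {
  ord <- order(dbs)
  dbs <- dbs[ord]; calls <- calls[ord]
  k <- length(dbs)
  if (rule == "first_positive") {
    for (i in seq_len(k)) if (calls[i] == 1) return(dbs[i])
    return(NA_real_)
  }
  for (i in seq_len(k)) {
    if (all(calls[i:k] == 1)) return(dbs[i])
  }
  NA_real_
}

# Random test trace: smooth low-frequency structure plus noise, on the
# canonical grid.
random_trace <- function(n = 244, duration = 10) {
  tt <- (seq_len(n) - 1) * duration / n
  v <- numeric(n)
  for (h in 1:4) {
    v <- v + stats::rnorm(1, 0, 1) * sin(2 * pi * h * tt / duration +
                                         stats::runif(1, 0, 2 * pi))
  }
  v + stats::rnorm(n, 0, 0.3)
}
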