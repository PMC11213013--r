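# Shared fixture builders (all data is generated in code at test time).

canon_times <- function(n = 244, duration = 10) (seq_len(n) - 1) * (duration / n)

gauss_bump <- function(center, width = 0.15, n = 244, duration = 10) {
  tt <- canon_times(n, duration)
  exp(-0.5 * ((tt - center) / width)^2)
}

# A clean five-bump trace with interleaved negative deflections, bump
# centres 1 ms apart starting at `first`.
five_bump_trace <- function(first = 1.5, spacing = 1.0, amp = 2,
                            n = 244, duration = 10) {
  centers <- first + spacing * (0:4)
  v <- numeric(n)
  for (k in 1:5) {
    v <- v + amp * (1 - 0.1 * k) * gauss_bump(centers[k], n = n, duration = duration)
    v <- v - 0.6 * amp * (1 - 0.1 * k) *
      gauss_bump(centers[k] + 0.45, n = n, duration = duration)
  }
  list(voltages = v, centers = centers)
}

make_waveform <- function(v, db = 80, freq = 12, subject = "m1")
  abr_waveform(v, subject, freq, db)

# Small deterministic batch: 2 frequencies x 3 levels.
small_batch <- function(seed = 1) {
  set.seed(seed)
  out <- list()
  for (f in c(12, 24)) for (d in c(20, 40, 60)) {
    out[[length(out) + 1L]] <-
      abr_waveform(round(stats::rnorm(244), 6), "m1", f, d)
  }
  out
}
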