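---
title: "Methods: automated ABR peak detection and threshold estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated ABR peak detection and threshold estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures implemented in `abrkit`,
their assumptions, the parameters that matter, and the design choices made
where the problem left the design open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The data model and the time grid

A waveform is `n` voltage samples covering a `duration`-ms post-stimulus
window; the canonical grid is 244 samples over 10 ms. Samples are treated
as values at times `t_i = t0 + i * duration/n` (`i = 0, …, n−1`), i.e. a
sampling *period* of `duration/n`, not a closed grid with both endpoints
included. This convention is deliberate: the three peak-search constants
(0.3689, 0.7377, 0.5738 ms) are integer multiples — 9, 18 and 14 — of
10/244 ms, so with this grid the search operates in exact whole samples and
nothing depends on floating-point rounding of ms values. The constants are
snapped to whole samples at run time in any case.

`resample_abr()` maps an arbitrary recording onto the canonical grid by
piecewise-linear interpolation. Windows longer than 10 ms are cropped;
shorter windows are rejected rather than extrapolated. Because the
canonical grid's last time (243·10/244 ≈ 9.959 ms) can fall beyond a coarse
input's last *sample* while still inside its recorded window, the last
recorded value is held constant over that sub-sample tail; this is a
within-window boundary rule, not extrapolation.

`smooth_abr()` is a discrete Gaussian convolution with bandwidth σ in
sample units (default 1.0), truncation radius `ceiling(4σ)`, and reflective
boundary (indices mirrored about the first/last sample, edge not
duplicated). These details are fixed so tests can build the exact kernel
oracle. Smoothing exists solely to stabilise extremum localisation;
every reported voltage is read from the unsmoothed trace.

## Two-step peak detection

Step 1 is a regression network mapping the standardized 244-sample trace to
the Wave 1 peak time. Architecture: two blocks of (width-9 then width-5
convolution, ReLU, width-2 max pooling, dropout 0.25), a 32-unit dense
layer, and a linear output; squared-error loss, Adam (learning rate 1e-3),
60 epochs, batch 32. The input is standardized per trace, so the regressor
keys on waveform shape rather than absolute amplitude, and the target is
z-scored internally — latencies span only ~0.5 ms of the 10-ms window, and
without target scaling the squared-error gradients are too small for stable
optimisation. The architecture details are configuration, not claims: the
contract is the regression task, and any seed-reproducible model meeting
the held-out error bounds is acceptable.

Step 2 (`fine_tune_peaks()`) refines τ̂₁ on the smoothed trace. The search
window starts `max(0, τ̂₁ − 0.3689 ms)`; strict local maxima are found by
neighbour comparison and thinned by *height-priority distance pruning*:
candidates are visited from tallest to shortest (ties: earlier index) and
kept only if no kept peak lies within 0.7377 ms. The first surviving
maximum is Wave 1; later survivors are Waves 2–5. Minima are treated the
same way at 0.5738 ms separation, and each wave's trough is the first
surviving minimum between its peak and the next. Height-priority pruning
(the behaviour of standard peak-finding routines with a distance argument)
matters: a first-come scan would latch onto any residual noise ripple in
the 9 samples ahead of the true peak, while under pruning such a ripple is
deleted by the much taller peak within its exclusion distance. The search
start window (9 samples) being smaller than the peak separation (18
samples) then guarantees that any seed estimate within ±0.3689 ms of the
true peak recovers it exactly. The search scans forward only, and troughs
are constrained to follow their peaks, so reported latencies are strictly
increasing across waves.

Below-threshold traces contain no gate: `detect_peaks()` returns whatever
extrema satisfy the constraints (or a typed `abr_no_peak` error for flat
traces). Screening belongs to thresholding, not to the peak finder. Waves
2–5 are reported but flagged `validated = FALSE`; only Wave 1 carries a
validated contract.

## Elastic time warping

`align_series()` registers a series' curves by warping each onto a
template. Curves are represented by their square-root slope functions
(SRSF) `q = f′/√|f′|`, under which the natural elastic distance is
invariant to reparameterisation; the optimal monotone, endpoint-fixed warp
is found by dynamic programming over lattice paths with segment slopes
restricted to {1/2, 2/3, 3/4, 1, 4/3, 3/2, 2} inside a ±2.5 ms band.
Capping segment slopes at 2 is a resolution safeguard: a slope-s segment
samples the source at s·Δ spacing, and with bumps ~0.15 ms wide a slope-4
segment (0.164 ms spacing) can clip a peak below a neighbouring wave. A
small roughness penalty (λ = 0.01 per unit time on `(√slope − 1)²`) breaks
ties toward the identity warp. The template is initialised as the
highest-energy waveform — the cleanest response, and a single-bump-per-wave
target, where the cross-sectional mean of unaligned curves can be multimodal
— then refined once as the mean of the aligned curves.

Warped curves take the original's values at reparameterised times
(amplitude/phase decoupling), so warping is appropriate before amplitude
analysis, FPCA, and the non-network classifiers, and is never applied
before latency reporting. `warp_features()` exposes the warping functions
themselves, subsampled, as monotone per-waveform phase covariates.

## Supervised threshold estimation

Waveform-level classification uses 246 features: the 244 voltages (warp-
aligned within each series for logistic regression and boosted trees; raw
for the network) plus stimulus level and frequency. The logistic model is
ridge-regularised (λ = 1e-3) on column-standardized features — with 246
correlated features and near-separable synthetic data, unpenalised maximum
likelihood does not converge meaningfully. Boosted trees (depth 4, η = 0.1,
150 rounds, single-threaded for determinism) consume unscaled features, as
trees are scale-invariant. The network applies three convolution/pooling
blocks to the standardized trace and concatenates the z-scored level and
frequency onto the flattened features before the dense layers — keeping
convolution purely temporal while letting the stimulus covariates inform
the decision.

Data splits are grouped by (subject, frequency): a series never straddles
train and test, since its waveforms share noise realisations of one ear and
leak trivially. The series threshold is the *monotone closure* of the
calls: the lowest level d with positive calls at d and every tested level
above it. On non-monotone call patterns this is deterministic and
conservative (isolated false positives below the response region are
ignored); `first_positive` is available as an alternative rule. All calls
negative yields the `NR` sentinel; all positive yields the lowest tested
level. Results carry a `step_valid` flag that is false when the tested
levels are more than 20 dB apart, the regime where level-by-level
thresholding stops being meaningful.

For synthetic corpora the waveform label is defined as
`db ≥ true threshold` — the generator's truth makes the labelling exact,
sidestepping the question of how human series-level judgements would be
propagated to individual waveforms in real data.

## Unsupervised threshold estimation

The pipeline for one series: elastic alignment (default on) → envelope
compression → FPCA → projection onto the first two principal components →
2-means clustering → monotone closure over the per-level cluster calls.

Plain FPCA scores of raw curves do not support the clustering step, for two
reasons established during design on the synthetic model. First, response
amplitude grows roughly linearly with level above threshold, and a 2-means
split of a long amplitude ramp falls mid-ramp, far above threshold. Each
curve is therefore rescaled to a saturating response envelope before FPCA:
with `r` the curve's RMS and `σ̂` the series noise floor (median across
curves of `mad(diff(v))/√2`, which is robust to the sparse, smooth
response transients), the curve is multiplied by `g(r)/r` where
`g(r) = 10σ̂·u/(1+u)`, `u = (r/1.5σ̂)⁴`. Noise-level curves (`r ≈ σ̂`) are
shrunk toward zero; any clear response saturates near a common scale, so
the clusters are "noise" and "response", not "low ramp" and "high ramp".
The half-saturation point, 1.5× the noise RMS, is the detection criterion:
responses below it are not distinguishable from noise by energy. Second,
clustering runs on *uncentered* projections onto the eigenfunctions, so
below-threshold waveforms sit near the origin of score space; centred
scores place the noise cluster opposite the signal mean, and which cluster
has the larger centroid norm then depends on the signal/noise mix of the
series rather than on responsiveness.

2-means clustering presumes the series actually mixes responsive and
non-responsive levels. Homogeneous series are decided directly from the
envelope: if every curve's RMS exceeds 3σ̂ all levels are called
responsive (threshold = lowest tested level), and if none does the series
is `NR`. In a homogeneous series the eigenfunctions are jitter directions
nearly orthogonal to the common waveform shape, so all scores collapse
toward the origin and clustering cannot distinguish uniformly-loud from
uniformly-silent series.

`cluster_scores()` itself follows the plain contract — k-means with k = 2,
10 restarts under a fixed seed, larger-centroid-norm cluster labelled
"above", ties and degenerate score sets labelled "below" — and `abr_fpca()`
is an unadorned eigendecomposition of the sample covariance on the common
grid (SVD of the centred curve matrix; eigenfunction signs fixed by making
the dominant loading positive). The compression and homogeneity guards are
pipeline glue in `unsupervised_threshold()`, not modifications of those
primitives.

## The synthetic generator

The generator emulates the morphology that all estimators rely on: five
Gaussian bumps (sd 0.15 ms) with interleaved negative deflections (60% of
bump height, 0.35 ms after each peak), base peak latencies
1.5/2.5/3.4/4.4/5.5 ms at threshold, latencies shrinking by 0.008 ms per dB
above threshold, Wave 1 bump height `0.15 µV/dB × (dB − threshold + step)`,
relative wave heights 1/0.85/0.6/0.7/0.5, additive white Gaussian noise of
0.1 µV, stimulus series 0–95 dB SPL in 5 dB steps, and per-(subject,
frequency) thresholds drawn from 20–60 dB. These values are realistic for
averaged mouse ABRs — Wave 1 near 1–1.5 ms, a few µV at high sensation
levels, tens-of-nanovolt noise after averaging, ~0.5 ms of latency
shortening over the level range. Gaussian bumps rather than more
biophysical shapes were chosen because their ground-truth extrema are
unambiguous; truth (per-wave peak/trough sample and voltage) is recorded
from the *pre-noise* trace as its exact grid extrema, so "exact recovery"
is well defined.

What the generator does not emulate — amplitude saturation at high levels,
electrical/myogenic artifacts, baseline drift, non-Gaussian noise,
frequency-dependent morphology — bounds what passing tests show: the
estimators are validated on the idealised signal model, and behaviour on
real recordings with those features is not claimed.

## Numerical and testing choices

Determinism is a contract everywhere: networks draw initialisation,
shuffling and dropout from R's RNG under a caller seed; boosted trees run
single-threaded; k-means uses a seeded 10-restart rule; repeated runs of
the batch pipeline produce byte-identical metrics CSVs. Degenerate inputs
have typed, tested behaviours (flat trace → `abr_no_peak`; constant curves
→ identity warps with a warning; zero-variance FPCA → degenerate flag;
single-class training sets, too-short series, under-covering windows →
errors).

Test problem sizes are chosen to exercise the estimators meaningfully while
keeping the default suite in the minutes range: the peak-search oracle runs
on 500 traces, the Wave 1 regressor trains on 800 synthetic traces with
~200 held-out waveforms from unseen subjects, the classifier comparison
uses a 1,000-waveform corpus (50 series), and the unsupervised estimator is
scored over 20 independent series. The acceptance script repeats these
measurements from scratch under a caller-supplied seed.

## Known limitations

Wave 1 is the only validated wave; Waves 2–5 inherit the alternation
contract but no accuracy claim. The unsupervised method assumes at least
four tested levels and a noise floor estimable from the series itself; a
series consisting entirely of marginal (~1–2σ̂) responses will read as
non-responsive. The warp search's slope cap (2) bounds how much local
compression a single pass can express; extreme misalignments (> 2.5 ms)
are outside its band. The CSV reader expects the documented wide dialect
(or a column mapping onto it); proprietary binary acquisition formats are
out of scope.
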