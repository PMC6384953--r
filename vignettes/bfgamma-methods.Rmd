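---
title: "Methods: gamma-event detection, spike-field coupling and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma-event detection, spike-field coupling and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models, parameters and
numerical choices. It states no empirical result that the test suite does
not itself compute.

## The experimental setting the package models

Recordings come from silicon probes with an attached optic fiber (optrodes)
in the ventral pallidum (VP) or medial septum (MS) of anesthetized mice
expressing halorhodopsin (NpHR) in somatostatin (SOM) cells. Green-light
illumination hyperpolarizes SOM cells; a recording session lasts 10 minutes
with laser ON for 5 s in every 20 s cycle, so each session yields 30 paired
trials of 5 s ON and the immediately preceding 5 s OFF. Under anesthesia the
local gamma rhythm slows to roughly 30 Hz, so "gamma" here means 20–40 Hz,
and the detector's search band is 20–80 Hz. Chronically implanted animals
receive trains of ten 1-s pulses at 0.5 Hz during open-field exploration
(randomly every 2–3 minutes) and 5 s/20 s cycles in the Y-maze.

All times are seconds from session start; intervals are half-open
`[onset, offset)` so spike membership in an epoch is unambiguous.

## Gamma-event detection

The detector is an envelope-threshold method for transient oscillations:

1. downsample to `target_fs` = 500 Hz (anti-alias low-pass, then decimate);
2. zero-phase band-pass 20–80 Hz with a two-way least-squares FIR filter of
   order `3 * round(fs / lo)` (76 taps at 500 Hz), transition bands of
   0.5 Hz treated as don't-care regions in the fit;
3. rectify and low-pass at 20 Hz (4th-order Butterworth magnitude, zero
   phase) to obtain a smooth envelope;
4. z-score the envelope with the mean and SD **of the whole signal**,
   including laser epochs;
5. events are excursions above 2 SD, extended on each side to the first
   1 SD crossing; events closer than the 150 ms refractory window are
   concatenated; events shorter than 150 ms are discarded;
6. each event is characterized with 7-cycle complex Morlet wavelets: the
   mean frequency is the power-weighted mean of the wavelet ridge over the
   event span, the amplitude (and the event "magnitude" used downstream) is
   the envelope z-score at the event peak.

Choices worth knowing:

* **Zero-phase filtering is done in the frequency domain** on a
  reflection-padded copy (realized gains are real and even). This makes two
  advertised properties exact by construction: detection is invariant to
  overall signal scaling, and time-reversing the input time-reverses event
  boundaries. Padded FFT lengths are rounded up to 2-3-5-smooth sizes;
  rough lengths make R's mixed-radix FFT an order of magnitude slower.
* **The event reference time for correlograms is the envelope peak.** The
  alignment point is otherwise unspecified in the field's descriptions; the
  peak is the least sensitive to boundary noise.
* **A degenerate (zero-variance) envelope yields no events** rather than an
  error, so all-zero channels pass through cleanly.
* **The detector has an intrinsic false-event rate on pure pink noise**
  (~0.29 events/s at default parameters): chance envelope excursions cross
  2 SD and survive the 150 ms criterion. This is a property of the method,
  not a bug; the suite regression-tests the rate into the band
  0.1–0.5 events/s. On burst-rich signals the whole-signal z-scoring
  inflates the envelope SD and pushes the noise floor below threshold, which
  also means near-threshold (≈3 SD) bursts lose a few percent sensitivity
  in heavily loaded signals — the sensitivity acceptance check therefore
  uses sparse injection, where amplitude-in-background-SD has its clean
  meaning.

## Photostimulation response of single units

`classify_unit()` compares per-trial ON rates with the paired pre-onset OFF
windows (`epoch_complement()`), two-sided Wilcoxon signed-rank at α = 0.05:
a significant decrease labels the unit suppressed (SOM+ by
photoinhibition), a significant increase excited, otherwise unaffected. The
field's descriptions do not state the classification test; Wilcoxon was
chosen because trial counts are small, paired and non-normal. Suppression
is `100·(r_off − r_on)/r_off`; a silent OFF condition leaves the modulation
undefined and the unit flagged.

Photoinhibition latency is read from a 10 ms PETH as the first post-onset
time at which the rate stays below `baseline mean − 2 SD` for three
consecutive bins. With moderate suppression (e.g. 50%) this criterion may
never be crossed — the latency is then `NA`, which is faithful: latency is
a functional-expression check for strongly silenced cells.

The sliding-sweeps test builds the event-aligned template (±15 s, 500 ms
bins, normalized to basal rate) and 100 surrogates by randomized exchange of
the inter-spike intervals and of the inter-onset intervals (each shuffle
preserves the ISI multiset exactly). With only 100 surrogates a two-sided
rank of the signed value cannot reach p < 0.01 (the minimum two-sided
empirical p is 2/101), so the per-bin test is a two-sided rank of the
**absolute deviation from the surrogate median**; its attained level is
1/101 ≈ 0.0099, matching the stated α, and the suite verifies the empirical
type-I rate against it.

## Spike-gamma coupling

* `spike_gamma_xcorr()` uses a circular-shift null: all event references are
  shifted by one common uniform offset modulo the session length, 500 times.
  This preserves both the event spacing and the spike autostructure, and is
  the conservative standard when what was shuffled in the original analysis
  is not stated. The coupled flag is one-sided (central-bin excess) at
  p < 0.05.
* `ppc()` uses the closed form `(|Σe^{iθ}|² − N)/(N(N−1))`, which equals the
  brute-force pairwise mean cosine to 1e−12 (tested) and is unbiased by
  spike count — subsampling half the spikes moves the estimate by < 0.02.
* `ppc_spectrum()` extracts spike phases by zero-phase band-passing the LFP
  to ±2 Hz around each grid frequency and interpolating the analytic
  signal (not the wrapped phase) at spike times.
* `rate_vs_gamma_amplitude()` pools units whose basal rate is > 0.8 Hz
  **and** inside the population interquartile range — the two filters are
  conflated in the original figure legend; the conjunction is this
  package's documented interpretation.
* `su_mu_coherence()` bins the reference unit and the summed remaining
  units at 500 Hz and computes multitaper coherence (TW = 3, K = 5) per 5-s
  epoch for the paired per-frequency Wilcoxon test; the condition-level
  spectra are computed from epoch-averaged cross- and auto-spectra, which
  reduces the 1/K small-sample bias of per-epoch coherence.

## Spectra

`multitaper_psd()` uses Slepian tapers from the tridiagonal formulation;
for windows longer than 1024 samples the tapers are computed exactly at
1024 points and spline-interpolated (shape error ~1e−5 against a reference
implementation). The PSD is one-sided over `0 < f < Nyquist` (DC and the
half-weight Nyquist bin are dropped); segments are demeaned, which removes
power within ~W of DC — flatness contracts apply above `2W`. Parseval holds
within 5%.

`psd_ratio_on_off()` averages per-trial ON/OFF PSD ratios, tests per
frequency bin (paired Wilcoxon, BH-FDR at q = 0.05) and excises bins within
2 Hz of 50 Hz mains. The default analysis range is ≤ 60 Hz: the gamma
hypothesis lives below 60 Hz, and testing hypothesis-free high-frequency
bins only dilutes the FDR correction. Note `E[X/Y] > 1` for noisy spectra,
so the mean ratio sits above 1 under the null; the per-bin test pairs raw
powers and is unaffected.

`gamma_band_power()` is the variance of the 20–40 Hz band-passed signal per
epoch, compared through the normality gate (Kolmogorov–Smirnov on the
paired differences, then paired t or Wilcoxon). The KS gate estimates the
normal's moments from the data (Lilliefors-style); this is the field's
convention and is documented rather than corrected.

## Behavior

Speed is `fps ×` frame displacement, smoothed with a 5-frame moving
average. Rest is smoothed speed below 1 cm/s sustained for ≥ 1 s — the
rest/run criterion is unstated in the field's descriptions and is a
parameter here. Laser-triggered averages filter triggers by the state at
onset. The alternation index scores a sliding window of 3 consecutive
entries as correct iff its arms are distinct; consecutive same-arm
detections are collapsed before scoring; the 30-s time course uses disjoint
blocks by default (overlapping available as an option).

`group_comparison()` gates every group through KS: all normal → t-test /
one-way ANOVA with pairwise Tukey; otherwise Wilcoxon rank-sum /
Kruskal–Wallis with BH-adjusted pairwise Mann–Whitney contrasts. The
two-way repeated-measures ANOVA named in the original statistics section is
attached to no result this package reproduces and is deliberately out of
scope.

## The synthetic world

The generator states one world and the tests measure recovery in it:

* **LFP**: 10-minute sessions at 500 Hz; 1/f pink background (unit
  exponent, 0.15 mV SD); an **ongoing narrowband gamma component**
  (Gaussian spectral profile, 30 ± 3 Hz, amplitude 1.5× the pink-band SD)
  that gives the spectrum its prominent gamma shoulder; and discrete
  Tukey-enveloped sinusoidal **bursts** (Poisson onsets at 0.4/s off-laser,
  mean 30 Hz, duration 0.15 s + Exp(0.15 s), plateau amplitude ~4× the
  total band SD). During laser ON in a VP-like world the burst rate is
  halved and the ongoing amplitude is scaled by 0.7 (halved power); an
  MS-like world has factor 1 for both.
* Bursts are thinned to ≥ 0.3 s separation so truth events stay separable
  by the 150 ms refractory detector. This dead time thins the denser OFF
  condition slightly more, shifting the expected detected ON/OFF density
  ratio from 0.50 to ≈ 0.55; recovery tests carry a 0.05 allowance for it.
* **Units**: 3 SOM+ (suppressed ×0.5 during ON), 5 excited (×1.5), 12
  unaffected; lognormal basal rates around 8 Hz; spikes by Bernoulli
  thinning on the 2 ms sample grid (an effective 2 ms refractory). SOM+
  spikes are von-Mises phase-locked (κ = 1.5, mean-rate preserving) to the
  burst oscillation while inside a true event. A per-event rate modulation
  shared across units is correlated with burst amplitude at target Pearson
  r = 0.25; its CV is 0.6 so that the structured component dominates
  Poisson counting noise when the correlation is re-estimated from spike
  counts.
* **Behavior**: speed is an OU process (τ = 1 s, σ = 0.5 cm/s) whose
  target switches between rest (0.3 cm/s) and run (8 cm/s) bouts with
  exponential durations — memoryless, hence time-reversible, so pre/post
  averages around random triggers are symmetric under the null. Trains
  whose first pulse lands in a rest bout add `speed_step` (default
  4 cm/s) to the target for the train span. Y-maze entries follow the
  Markov rule: with probability `alternation_p` enter the arm not visited
  in the last two entries, else return to the previous arm, making the
  expected index exactly `100p`.

What the generator does **not** emulate: volume conduction and
multi-channel structure, non-stationary anesthesia depth, spike-sorting
artifacts, theta rhythms, movement artifacts in the LFP, and any coupling
between behavior and electrophysiology. A green recovery test therefore
establishes that the analysis recovers its stated world's parameters — not
that it is robust to every failure mode of real recordings.

## Scaling of the test suite

Monte-Carlo scales follow the stated acceptance criteria (100 seeded
sessions for detector sensitivity, ≥100 null units for the permutation
nulls, 20 seeds for fixture recovery, 50 seeds for the behavioral step);
where a module example quotes a larger world than needed for a unit test
(e.g. 100-seed Rayleigh calibration), the unit test runs a scaled-down
version (30 seeds) and the acceptance suite carries the stated scale. The
whole suite runs in about 4 minutes on one CPU.
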