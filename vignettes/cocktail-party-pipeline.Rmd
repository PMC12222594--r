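---
title: "Speech-evoked ERPs, linear models and attention decoding: methods"
author: "edgeTRF authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech-evoked ERPs, linear models and attention decoding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the assumptions they carry, the defaults and why they were
chosen, and the places where a design decision was genuinely open.

## The model

The package treats the EEG response to continuous speech as a superposition
of transient evoked responses to *acoustic edges* — salient intensity
rises in the speech envelope. At channel $n$,

$$ r(t, n) = \sum_{l=1}^{L} s(t - \tau_l)\, h(\tau_l, n) + \epsilon(t, n), $$

where $s$ is the single-channel onset envelope, $h$ the temporal response
function over lags $\tau_1 \dots \tau_L$, and $\epsilon$ everything the
linear model does not capture. Selective attention acts multiplicatively on
the N1 deflection of $h$: the attended stream's kernel has a full-size N1,
the ignored stream's a reduced one. Everything the package computes — ERPs
time-locked to threshold crossings, ridge-estimated TRFs and decoders,
theta-band phase consistency — is a different estimator of (a functional
of) this same generative picture.

Key assumptions: linearity and time-invariance of the evoked response
within a trial; independence of the two streams' edge processes; additive
background activity with a 1/f spectrum that is not phase-locked to either
stream.

## The envelope chain

Audio is decomposed by a 4th-order IIR gammatone filterbank (Slaney-style
coefficients, ERB-rate spaced centers; 128 bands within 100–8000 Hz by
default). Per band, the Hilbert-envelope magnitude is raised to the 0.3
power — a fixed loudness-growth compression — and bands are averaged into
the broadband envelope. A zero-phase 3rd-order Butterworth low-pass at
25 Hz, a first difference and half-wave rectification yield the onset
envelope. The first difference is not scaled by the sampling rate: every
downstream threshold is expressed in pooled-sigma units, which are
invariant to a global scale factor. The gammatone filter order and ERB
formula are implementation choices — the gammatone literature admits
several — and are stated here rather than left implicit.

All filtering in the package follows one convention: Butterworth designs
with 3 dB attenuation at the cutoff, applied forward and backward
(`signal::filtfilt`), so the net response is 6 dB down at the cutoff and
the phase is exactly zero. Resampling (44.1 kHz audio to the 256 Hz
analysis rate; 512 to 256 Hz EEG) is Fourier-domain truncation, which is
anti-aliased by construction; trial edges, where FFT periodicity and filter
warm-up leave artifacts, are discarded (1 s per side) before any analysis.

## Triggers and ERPs

Per subject, all onset envelopes (2 streams × all trials) are pooled and
the *population* standard deviation $\sigma_{env}$ computed across every
sample — with pools of ~10⁶ samples the population/sample distinction is
negligible, and the population form matches the "across all amplitude
values" definition. A trigger sits at every sample whose predecessor was at
or below $2\sigma_{env}$ and which itself is above; the first sample has no
predecessor and can never trigger; no refractory period is imposed. Pooling
happens after decimation to 256 Hz, the order in which the chain produces
the data.

Epochs span −500..2000 ms around each trigger (sample offsets
`round(w·fs)`, so 641 samples at 256 Hz), are baseline-corrected by the
−50..0 ms mean, and rejected whole if any channel exceeds ±100 µV.
Sweep counts are then matched between conditions by a seeded uniform random
subset of the *per-subject* minimum. (The study-scale analogue uses the
minimum across subjects and conditions; with the generator's stable
trigger statistics the per-subject minimum differs by at most a few
percent and keeps the cohort loop single-pass.) Component windows are
derived at the group level: N1 and P2 peak latencies are searched on
the attended-condition grand average at the peak-topography channel within
80–180 ms (negative) and 180–280 ms (positive) — the search windows themselves are a
package choice — and
per-subject amplitudes are windowed means (±20 ms) at those fixed centers
for both conditions. N1-P2 is the P2 minus the N1 windowed mean.

## Morse wavelets and WPSS

The analytic generalized Morse wavelet is built in the frequency domain,
$a\,\omega^\beta e^{-\omega^\gamma}$ for $\omega > 0$ and exactly zero for
$\omega \le 0$, with $(\gamma, \beta) = (3, 3.29)$: maximal time–frequency
symmetry with about one oscillation cycle ($\sqrt{\beta\gamma}/\pi \approx
1.00$) at the peak frequency inside the central energy window. "Center
frequency" means the spectral peak $\omega_p = (\beta/\gamma)^{1/\gamma}$
mapped to Hz — the standard Morse parameterization and the one consistent
with the one-cycle footprint arithmetic. The scale grid is geometric with
17 voices per octave and *inclusive* endpoints 2 and 32 Hz (69 scales);
endpoint inclusion was an open choice and is fixed here.

The transform is the inner product with the conjugated, shifted kernel;
kernels are unit-energy. WPSS at a time–frequency cell is the mean
resultant length of the sweeps' instantaneous phases: 1 under perfect
phase locking, with expectation $\sqrt{\pi}/2 \cdot K^{-1/2}$ for $K$
uniform phases. Zero-magnitude coefficients contribute a zero vector and a
logged count, keeping the measure defined on degenerate inputs. Transforms
run on the full −500..2000 ms epoch and only the −50..500 ms span is
reported, so cone-of-influence contamination stays outside the reported
window. For the per-channel scalar measure (theta band 4–8 Hz × N1−20 ..
P2+20 ms window) the resultant is computed over a seeded random subsample
of 400 matched sweeps: the estimator's small-sample bias is identical
across conditions, its variance at K = 400 is negligible relative to the
attention effect, and the cost of the resultant scales linearly in K.

## Ridge models

Both model directions solve the stated normal equations exactly — no
eigenvalue-mean rescaling of λ, no intercept column (all signals are
centered/normalized first), no cross-validation. Training uses 20
log-spaced penalties from 10⁻⁶ to 10⁶ and averages the 20 weight sets with
equal weights. Internally the average is computed from one symmetric
eigendecomposition of XᵀX per design (mathematically identical to 20
separate solves; eigenvalues are clamped at zero against rounding).
Trials enter the normal equations as separately built, zero-padded designs,
so lag windows never straddle trial boundaries.

The decoder is evaluated leave-one-trial-out: one decoder per training
trial (each already λ-averaged), averaged with equal weights and applied to
the held-out trial; accuracy is the Pearson correlation with the true
envelope, averaged over folds. An equally defensible scheme concatenates
the training trials into one solve; that variant is available via `scheme = "concatenated"` in
`looReconstruction()` for sensitivity analysis. Channel-wise decoding
shares each trial-channel's autocovariance between the attended and ignored
solves.

TRF postprocessing: 30 Hz zero-phase low-pass along the lag axis, baseline
correction by the −50..0 ms lag mean, trimming of the 200 ms buffers so the
−250..700 ms grid reports −50..500 ms.

## ERP–TRF comparison

The cross-correlation lag between ERP and TRF is found by maximizing the
participant-mean normalized cross-correlation at the peak-topography
channel over ±32 samples (±125 ms); both the designated-channel choice and
the search range are package decisions. Topographic similarity is the per-sample Pearson correlation
across channels (r₂D), which requires at least 3 channels — degenerate
inputs are rejected rather than returning NaN — and per-channel waveform
similarity is the correlation along time over −50..500 ms.

## Group statistics

Paired t-tests are one-tailed for the attended > ignored direction. The
cluster-mass permutation test thresholds the two-tailed paired-t map at the
p = 0.01 critical value, forms sign-homogeneous connected clusters
(temporal adjacency in 1-D; 4-connectivity in time–frequency, with no
cross-channel clustering — correction is within channels), scores them by
summed |t|, and compares each mass against the permutation null of the
maximum mass under random within-subject sign flips (full enumeration when
2ⁿ ≤ the permutation budget). Sign flips and condition-label permutations
are equivalent for paired designs; flips were chosen. Positive and negative
clusters are scored separately against the same max-null. Permutation
p-values are (1 + #{null ≥ mass})/(nPerm + 1) and significance is mass
above the (1 − 0.05) null quantile.

## The synthetic generator

The generator emulates the *structure* of a two-speaker selective-attention
EEG study: per subject, 20 trials of 50 s at 256 Hz with two concurrent
onset-envelope pulse trains and EEG formed by kernel convolution plus 1/f
noise. Defaults, chosen once:

* **Inter-onset intervals**: gamma, shape 2, mean 1/rate — irregular but
  non-Poisson spacing, like syllabic timing.
* **Pulse rate 3.4/s, width σ 5 ms, log-normal amplitudes (meanlog 0,
  sdlog 0.7)**: Campbell's-theorem calibration puts ~79 % of pulses above
  the pooled 2σ threshold, giving ~2.7 suprathreshold triggers per second,
  a realistic edge rate for narrated speech. The 5 ms
  width keeps the threshold-crossing-to-pulse-peak delay near 6 ms, so the
  ERP N1 lands within a few ms of the kernel's 135 ms latency and the TRF
  leads the ERP by 1–2 samples.
* **Kernels**: attended P1 +0.5 µV @ 80 ms (σ 15), N1 −1.0 µV @ 135 ms
  (σ 22), P2 +0.8 µV @ 225 ms (σ 30); ignored N1 × 0.4, the attention
  effect of interest.
* **Topography**: unit-norm Gaussian fall-off around a designated
  "Cz-like" channel — a frontocentral distribution.
* **Noise**: spectrally shaped Gaussian, exponent 1 (periodogram slope −1),
  independent across channels by default; a spatially correlated variant
  sits behind a flag. **SNR −10 dB** per trial (evoked power over noise
  power, pooled over channels): a realistic single-sweep regime for
  cortical ERPs — single sweeps are dominated by noise and all effects
  must emerge through averaging, regression, or phase pooling.

What the generator does **not** emulate: speech acoustics (no intelligible
waveforms, no spectro-temporal structure beyond edge timing), reverberation
or spatialization, eye/muscle artifacts and bad channels (the 100 µV
rejection stage therefore idles on clean synthetic data), volume-conduction
correlations of the background activity, and any nonlinearity or adaptation
of the evoked response. Passing tests on this cohort demonstrate that the
estimators recover what the generative model plants — not that real EEG
satisfies the generative model.

## Problem sizes

The test suite and the acceptance script size their simulations for a
single-CPU desk run: parameter recovery uses the full default cohort (12
subjects × 20 trials × 50 s, 16 channels — 64-channel montages are
supported but add nothing to the recovery question); the replicate check of
the four attention effects uses ten seeded cohorts of 6 subjects × 10
trials × 30 s at 8 channels, where every stage still runs end to end; the
permutation-calibration null uses 500 datasets at 1000 permutations.
Generator *parameters* are identical across all of these — only cohort
geometry is scaled.

## Known limitations

* The gammatone realization and ERB spacing are one defensible choice among
  several; center frequencies are reproduced to filter-design accuracy, not
  bit-identical to any other toolbox.
* Fourier resampling assumes quasi-stationary content at trial edges;
  edges are trimmed downstream, but envelopes shorter than a few filter
  warm-ups are rejected rather than padded.
* `matchSweepCounts` equalizes within subject; across-subject count
  equalization would need a two-pass cohort loop.
* The λ-grid average stabilizes regularization across subjects and
  conditions but does not optimize predictive accuracy, and recovery correlations are reported
  after lag alignment for that reason.
* Permutation p-values inherit Monte-Carlo noise of order 1/√nPerm; the
  seed is explicit everywhere so runs are exactly repeatable.
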