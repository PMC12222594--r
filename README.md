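# edgeTRF

Selective attention to one of two concurrent speakers leaves a robust
signature in the EEG: every salient intensity rise in the speech envelope
(an *acoustic edge*) evokes a P1–N1–P2 response, and attention enhances the
N1 deflection of the attended stream. The same enhancement is what drives
the two linear-modelling workhorses of the neural speech-tracking
literature — forward temporal response functions (TRFs) and backward
stimulus reconstruction (SR). `edgeTRF` implements the full analysis chain
that links the two views, for researchers who work with cocktail-party EEG
or want a tested desk-scale replica of such an analysis.

## What the package computes

**Onset envelopes.** Speech audio is decomposed by a 128-band gammatone
filterbank (ERB-spaced, 100–8000 Hz), Hilbert envelopes are compressed by
the power law x^0.3 and averaged; the broadband envelope is low-passed at
25 Hz, differentiated and half-wave rectified, yielding a train of
Gaussian-like pulses s(t) that mark acoustic edges.

**Speech-evoked ERPs.** Per subject, all onset envelopes are pooled, the
global standard deviation σ_env is computed, and triggers are placed at
every sub- to supra-threshold crossing of 2σ_env. EEG (1–45 Hz band-pass,
30 Hz low-pass, 1 s edge trims) is epoched from −500 to 2000 ms around each
trigger, baseline-corrected (−50..0 ms), sweeps exceeding ±100 µV are
rejected, and per-condition sweep counts are matched by seeded random
selection before averaging.

**Forward/backward models.** With lagged stimulus matrix **S** (lags
−250..700 ms) the TRF is the ridge solution

    h = (SᵀS + λI)⁻¹ Sᵀ r

and the decoder, with lagged multichannel EEG **R** (lags 0..500 ms),

    g = (RᵀR + λI)⁻¹ Rᵀ s .

Both are trained on 20 log-spaced λ between 10⁻⁶ and 10⁶ and the weights
averaged (no cross-validation). SR accuracy is the Pearson correlation
between the reconstructed and true envelope under leave-one-trial-out
evaluation, where the per-trial decoders of the training trials are
averaged and applied to the held-out trial. TRFs are low-passed at 30 Hz,
baseline-corrected like the ERPs and trimmed to −50..500 ms for comparison.

**Phase consistency (WPSS).** Single sweeps are transformed with analytic
generalized Morse wavelets ψ(3, 3.29) (17 scales per octave, 2–32 Hz); the
wavelet phase synchronization stability at each time–frequency cell is the
mean resultant length |K⁻¹ Σₖ exp(i φₖ)| of the instantaneous phases across
sweeps, reduced to a scalar attention measure by averaging over the theta
band (4–8 Hz) inside the N1–P2 window.

**Statistics.** One-tailed paired t-tests on attended/ignored measure
pairs, channel-wise t-maps with topographic correlations r₂D, and
cluster-mass permutation tests (sign-flip null, 10000 permutations,
thresholds 0.01/0.05) for waveforms and time–frequency maps.

**Synthetic cohorts.** Because the real recordings are not shipped, a
seeded generator produces two-speaker cohorts with known ground truth:
gamma-spaced Gaussian pulse trains per stream, convolution with a P1-N1-P2
kernel whose N1 is attenuated for the ignored stream, projection through a
frontocentral topography, and 1/f noise at a configurable per-trial SNR.
Every stage of the pipeline is testable against this ground truth.

## Worked example

```r
library(edgeTRF)

spec <- cohortSpec(nSubjects = 4, nTrials = 8, trialDurationS = 30,
                   nChannels = 8, seed = 42)
an <- cohortAnalysis(spec)
```

The analysis prints, for this seed:

```
trigger rate: 2.66 events/s
ERP peaks (Cz): N1 140.6 ms, P2 226.6 ms
TRF peaks (Cz): N1 132.8 ms, P2 226.6 ms
TRF-kernel recovery r: 0.996
erpN1p2     group t at Cz:  24.15
trfN1p2     group t at Cz:  46.57
wpssTheta   group t at Cz:   6.88
srAccuracy  group t at Cz:  37.12
best ERP-TRF lag: 1 samples
```

Reading: acoustic edges cross the pooled 2σ threshold about 2.7 times per
second; the grand-average ERP shows its N1 near 140 ms (the generating
kernel places it at 135 ms; the threshold crossing slightly precedes the
pulse peak, so the ERP lags the TRF by a sample or two); the postprocessed
TRF is nearly identical to the generating kernel (r = 0.996); and all four
attention-decoding measures — ERP and TRF N1-P2 amplitudes, theta-band
WPSS, and SR accuracy — separate attended from ignored streams with large
positive group t statistics at the peak-topography channel.

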