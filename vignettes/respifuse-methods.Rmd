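---
title: "Respiratory rate from fused ECG/PPG modulations: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory rate from fused ECG/PPG modulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respifuse)
```

## The estimation model

Breathing couples into the cardiovascular system along three pathways, and
each leaves a beat-synchronous trace in ECG and PPG. Thoracic impedance
changes and cardiac axis rotation modulate the projected QRS amplitude;
respiratory sinus arrhythmia (vagally mediated) modulates the heart
period; and intra-thoracic pressure swings move the baseline. Sampling
these effects once per beat gives six respiratory modulated components
(RMCs): amplitude (EAM, PAM), interval (EFM, PFM) and baseline (EBW, PBW)
series from the two signals. Under regular breathing each series is, to
first order, a sinusoid at the respiratory frequency buried in
measurement noise and beat-to-beat variability — so the respiratory rate
is a spectral-peak estimation problem, and the six series are six noisy
views of the same underlying oscillation.

The pipeline denoises each view (variational mode decomposition), scores
how respiratory-like each one is (a spectral concentration index),
discards the poor views (adaptive threshold), and combines the good ones
in the *time domain* through their first principal component before a
single spectral readout. Time-domain fusion is the core design commitment:
averaging spectra or averaging per-component rate estimates discards the
phase coherence between components, whereas the first principal component
of phase-aligned series reinforces the common oscillation and averages
out component-specific noise.

Windows where a stage fails — no detectable beats, fewer than four usable
cycles, a degenerate spectrum — are flagged, never silently dropped, so
coverage is always visible in the output.

## Stage-by-stage choices

### Preprocessing

Each 30 s window is resampled to 300 Hz (windowed-sinc interpolation,
Hann-tapered kernel, 16 zero-crossings; the kernel cutoff is lowered when
downsampling so the result stays alias-free), smoothed with a 10-point
centered moving average (reflective padding; at 300 Hz an even length
leaves a 1.7 ms residual asymmetry, well below fiducial tolerances), and
high-passed with a third-order 0.05 Hz Butterworth filter.

The high-pass is applied forward–backward so the chain has zero phase and
fiducial timing is preserved; the effective attenuation is therefore the
squared magnitude response. At a normalized cutoff of 3×10⁻⁴ the filter's
start-up transient spans several seconds, so each pass is initialized at
the filter's steady state for the *edge-local mean* of the signal
(0.25/f_c ≈ 5 s of samples) rather than the first sample alone: a QRS
complex that happens to sit on the window edge would otherwise be
mistaken for baseline level and inject a long decaying artifact. With
this initialization a constant input is annihilated to machine precision
and a 0.01 Hz drift is attenuated by the analytic squared-Butterworth
factor (≈ 6.4×10⁻⁵).

### Fiducial detection

R peaks come from the classical Pan–Tompkins chain (5–15 Hz band-pass,
five-point derivative, squaring, 150 ms integration, adaptive
signal/noise thresholds, 200 ms refractory, half-threshold search-back),
with two implementation details worth noting: integrator local maxima are
collapsed per refractory span to the tallest candidate before
thresholding (the integrator ripples, and its per-beat maximum is what
tracks the QRS), and accepted peaks are mapped to the raw-ECG maximum
within ±50 ms so indices sit on the R apex. Q is the signal minimum in
the 200 ms before each R; beats whose search interval precedes the window
are dropped. Inter-beat intervals outside 0.3–2.0 s reject the
smaller-amplitude peak.

PPG onsets use a slope-sum detector: the windowed sum of positive slopes
(128 ms) of the lightly smoothed waveform peaks on every systolic
upstroke; peaks are kept above 30% of the running 90th percentile (2 s
context) with a 300 ms refractory. The onset is then marked at the *foot
of the upstroke* — the last pre-upstroke sample whose slope is below 5%
of the cycle's maximum slope. Foot marking matters: the naive "waveform
minimum before the upstroke" migrates toward the search-window edge
whenever the respiratory baseline rises faster than the diastolic tail
decays, which happens on every rising-baseline quarter of the respiratory
cycle. The slope criterion is invariant to baseline slope and keeps
onsets within ±20 ms on clean signals and 100% detection at 20 dB SNR.
The systolic peak is the maximum within 125 ms after the onset.

### Beat series and uniform resampling

Amplitude and baseline values are stamped at their R/systolic-peak time;
interval values at the interval midpoint. The irregular series are
cubic-spline interpolated (Forsythe–Malcolm–Moler end conditions, exact on
cubics) onto the absolute 10 Hz lattice k/10 s, restricted to the span of
observed beats — no extrapolation — and mean-subtracted. Using one
absolute lattice for all components lets the filtered series be aligned
sample-by-sample for fusion without a second interpolation. 10 Hz is
comfortably above the 0.75 Hz band edge while keeping 30 s windows at
~300 samples, where the decomposition is fast; spectral resolution is set
by the window length, not the rate.

### Variational mode decomposition

Each uniform series is decomposed into K = 5 band-limited modes by the
standard ADMM iteration: Wiener-filter mode updates around each center
frequency, center-frequency updates as the one-sided spectral centroid,
sequential (Gauss–Seidel) sweeps, and an optional dual ascent (τ = 0 by
default, which omits the exact-reconstruction constraint — the robust
choice for noisy data). Remaining parameters are the customary defaults
(α = 2000, tolerance 1e-7, at most 500 iterations, uniform
center-frequency initialization over the half-band); all are exposed in
the configuration. The input is mirror-extended by half its length per
side and the modes cropped back, the standard treatment for boundary
splatter; the residual edge transient decays like 1/√n, which is why
single-tone identity checks in the tests use multi-minute tones. The mode
whose periodogram peak (Hann window, 4096-bin zero padding) lies closest
to the input's peak is kept as the denoised component; ties go to the
lower mode.

Non-convergence at the iteration cap is flagged (`vmd_unconverged`) but
the result is still used — the mode estimates are usable long before the
strict tolerance is met.

### Quality screening

The respiratory quality index of a zero-mean series is the fraction of
its spectral power (plain DFT of the series as-is — no taper, no padding,
magnitude-squared coefficients) that falls inside 0.05–0.75 Hz,
equivalently 3–45 breaths/min. The DC bin is excluded from the total:
series are mean-subtracted upstream, and including a numerically nonzero
DC residual would make the index depend on centering precision. The index
is scale-invariant, equals a²/(a²+b²) exactly for an in-band/out-of-band
tone pair of amplitudes a and b on integer-period grids, and is monotone
in in-band energy.

Within a window the adaptive threshold T is the arithmetic mean of the
available components' indices; components scoring ≥ T are fused. Since
the maximum is never below the mean, at least one component always
survives. Components missing because one channel failed are excluded from
the mean rather than scored zero — scoring them zero would bias T
downward and admit poor components. Because screening runs *after* VMD
filtering, all six indices are compressed toward 1; the mean threshold
still ranks them, which is its purpose.

### PCA fusion and readout

The m selected series, on their common grid overlap, form the columns of
X. Columns are centered, and by default scaled to unit variance before
the covariance eigendecomposition: interval components are measured in
seconds (~10⁻² magnitude) and amplitude components in signal units, and
unnormalized covariance PCA would let the arbitrary unit choice decide
the loadings. The literal centering-only behavior remains available via
`normalize_rmcs = FALSE`. The fused waveform is the projection onto the
unit leading eigenvector, its sign fixed so the largest-magnitude loading
is positive (PCA sign is arbitrary and irrelevant to the spectral peak;
determinism aids testing). Eigenvalues are sorted descending with ties
resolved by original column order.

The rate is 60× the frequency of the maximum of the fused waveform's
Hann-windowed periodogram, zero-padded to 2¹⁴ bins, inside the closed
band [0.05, 0.75] Hz. At a 10 Hz series rate the padded grid is ≈ 0.04
breaths/min — far below the windowing-induced uncertainty, so no peak
interpolation is performed; ties go to the lower frequency. A raw 30 s
window would otherwise quantize the rate to 2 breaths/min steps.

### Error metrics

ME is the mean estimate-minus-reference difference, STD the sample
standard deviation of the differences (n−1), MAE the mean absolute
difference, and RMSE the root mean square difference (n), which links the
four through RMSE² = ME² + STD²(n−1)/n. Bland–Altman agreement is the
bias with ±1.96 SD limits. Cohort aggregation reports both per-record
summaries and a pooled summary over the concatenation of all window
pairs, because published dataset-level figures rarely state which pooling
they use. Pairs with a missing estimate are excluded and counted, keeping
window loss visible.

## The synthetic generator

`generate_record()` emulates exactly the modulation mechanisms the
pipeline targets. A single beat-time process drives both channels
(matching physiology and enabling cross-signal fusion tests): beats are
laid down with instantaneous period 60/HR + d_fm·sin(φ(t)), where φ is
the respiratory phase — a fixed rate by default, a linear chirp when a
second rate is given. The ECG renders a fixed Gaussian P-QRS-T template
per beat with QRS amplitudes scaled by 1 + d_am·sin(φ); the PPG renders a
pulse (1−e^(−s/30 ms))·e^(−s/250 ms) starting 0.2 s after each beat with
amplitude scaled analogously. Both channels add a sinusoidal respiratory
baseline and white noise at a configurable SNR; a sinusoidal reference
respiration trace and a 1 Hz instantaneous-rate channel are bundled.

Fixed templates (rather than a dynamical heart model) are deliberate:
fiducial ground truth must be exact by construction. The R apex sits at
the beat time, the Q trough 25 ms earlier; the PPG pulse is zero at its
onset with a fast upstroke and slow diastolic decay, so the composite
waveform's minimum falls exactly on the onset, and the systolic-peak
truth is read off the rendered noise-free composite.

Default depths (10% ECG amplitude, 50 ms RSA, 20% pulse amplitude,
baseline amplitudes of 0.05/0.1 signal units, 20 dB SNR) sit in the
middle of what bedside recordings show; they are study conditions, not
tuning knobs. One validity constraint is enforced: the respiratory tone
must stay below the beat-domain Nyquist rate (RR/60 < HR/120), since a
once-per-beat sample stream cannot represent a faster modulation — the
generator rejects such configurations rather than silently aliasing.

What the generator does *not* emulate bounds what green tests prove:
there are no motion artifacts, no ectopy or arrhythmia, no pulse-shape
morphology changes, no sensor dropout, and breathing is strictly
(quasi-)sinusoidal. Results on real data depend on exactly these
nuisances; the generator establishes correctness of the machinery, not
clinical performance. Two generator couplings are physiological and worth
knowing when reading tests: QRS scaling moves EAM and EBW together (they
share a mechanism), and interval modulation leaks weakly into PAM/PBW
through the overlap of diastolic tails at varying beat spacing.

## Numerical behavior and degenerate inputs

* Indices are 1-based everywhere, following R convention; windows are
  half-open in time.
* Argmin/argmax fiducial ties resolve to the earliest index; the PPG foot
  search resolves ties to the latest pre-upstroke index so a flat
  diastole yields the foot of the rise.
* The zero-phase high-pass is exactly linear up to IIR floating-point
  accumulation (~10⁻⁷ relative for poles at |z| ≈ 0.9995).
* Between 30 and 0 dB SNR the end-to-end estimate is bias-limited
  (median error 0.2–0.35 breaths/min on the study grid, dominated by
  spline/decomposition edge effects rather than noise); degradation
  becomes visible around −10 dB. Tests assert this shape rather than
  strict monotonicity in SNR, which does not hold in the bias-limited
  regime.
* Flat channels, too-few beats, and zero-power spectra raise classed
  conditions that the pipeline converts to per-window flags; a window
  with no usable component reports an `NA` rate, never a fabricated one.
* Problem sizes in the test suite are chosen for desk-scale runs: 30–120 s
  records for pipeline tests, 45 records (60 s each) for the recovery
  grid, 100 random signals for each oracle cross-check.

## Known limitations

* The RQI spread after VMD filtering is narrow (all components look
  respiratory-band-concentrated once denoised); screening before
  filtering would separate components more but departs from the stated
  processing order.
* The WFDB reader covers headers plus signal formats 16 and 212 — enough
  for the common open ECG/PPG datasets, not the full format zoo.
* No artifact/quality gating of the raw waveforms beyond the stated
  preprocessing; heavily corrupted segments surface as flagged windows
  rather than being repaired.
* Rates at the band edges (near 3 or 45 breaths/min) lose accuracy first:
  the high-pass grazes the lower edge and beat-domain sampling limits the
  upper edge at low heart rates.
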