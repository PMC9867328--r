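---
title: "Comparing EEG feature sets for valence–arousal emotion classification"
author: "fractalEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing EEG feature sets for valence–arousal emotion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalEEG)
```

## The problem

Affective neuroscience and affective-computing applications often reduce
emotion to two orthogonal dimensions of the circumplex model — valence
(pleasantness) and arousal (activation) — and ask whether short segments of
scalp EEG can be classified as *high* or *low* on each dimension, using the
participant's own self-report as ground truth. A large number of EEG signal
descriptors ("features") have been proposed for this task; which family of
features carries the most discriminative information is an empirical
question. This package implements a complete, reusable pipeline for that
comparison: signal conditioning, five per-channel per-epoch feature sets,
subject-dependent nested cross-validated classification with two
classifiers, and paired statistics comparing the feature sets. Because the
established emotion-EEG corpora are license-gated, the package also ships a
synthetic-EEG generator that plants known class differences, so every stage
is testable end-to-end and the pipeline's ability to recover a planted
effect can be measured exactly.

## Signal conditioning

Raw multichannel recordings (microvolts) pass through a fixed chain:

1. **Mains notch** — second-order IIR biquad at 50 or 60 Hz, quality factor
   Q = 30 (configurable), applied forward–backward (zero phase).
2. **High-pass** — 4th-order Butterworth at 1 Hz, zero phase; removes DC
   offset and electrode drift.
3. **Down-sampling to 128 Hz** — Fourier (band-limited) resampling: the
   spectrum is truncated at the new Nyquist frequency and inverted at the
   new length. This is delay-free; a polyphase FIR implementation we
   evaluated introduced an uncompensated group delay of about one sample.
4. **Common average reference** — the instantaneous cross-channel mean is
   subtracted, so per-sample channel sums are zero (and the operation is
   idempotent).
5. **Epoching** — non-overlapping 2 s windows of exactly 256 samples;
   a trailing partial window is dropped.
6. **Artifact rejection** — an epoch is discarded iff any sample on any
   channel strictly exceeds 100 µV in magnitude. An epoch peaking at
   exactly 100 µV is kept. The bound is applied after re-referencing,
   i.e. on the data the classifier will see.

Zero-phase filtering was chosen because filter latency would otherwise
shift feature values differentially across frequencies within the short
2 s epochs. Whether the amplitude rule should bind per channel or jointly
is not standardized in the field; we reject when *any* channel exceeds the
bound, which is the conservative choice.

Trial-level self-report ratings are binarized at the conventional midpoint
threshold — half the scale maximum, i.e. 4.5 on a 1–9 scale and 2.5 on a
1–5 scale — with the high class defined by `rating >= threshold`. Data
whose labels are already binary pass through unchanged.

## The feature sets

All features are computed per channel per epoch (T = 256 samples). With 14
channels the five sets provide 9, 24, 3, 2 and 4 features per channel
respectively — 42 per channel, 588 in total.

**Statistical (9).** Mean, median, population standard deviation
$\sigma_X$, skewness and kurtosis (standardized third/fourth central
moments; kurtosis is non-excess, so a Gaussian signal scores 3), the mean
absolute first and second differences
$\delta_X = \tfrac{1}{T-1}\sum |X(t{+}1)-X(t)|$ and
$\gamma_X = \tfrac{1}{T-2}\sum |X(t{+}2)-X(t)|$, and their normalized
forms $\delta_X/\sigma_X$, $\gamma_X/\sigma_X$. All moments use the
population (1/T) normalization consistently. A zero-variance epoch defines
the normalized quantities, skewness and kurtosis as 0 (with a warning)
so classifiers never see missing values.

**Wavelet (24).** A continuous wavelet transform with the analytic Morlet
wavelet (centre angular frequency $\omega_0 = 6$), L1-normalized
($1/|a|$), evaluated at 12 scales whose pseudo-frequencies form a fixed
near-geometric ladder from 61.115 Hz down to 1.48 Hz (ratio ≈ 1.402; all
scales above 1.25 Hz). The features are the per-scale mean and population
SD of the coefficient magnitudes. The ladder is pinned to printed
frequencies rather than derived from any toolbox's internal scale
convention, which makes outputs reproducible across implementations.

**Fractal dimension (3).** Three estimators of waveform complexity
(1 = smooth curve, 2 = plane-filling roughness):

- *Katz*: with curve length $L = \sum|\Delta x|$, diameter
  $d = \max_t |x(t)-x(1)|$ and step count $n = T-1$,
  $\mathrm{KFD} = \log n \,/\, (\log n + \log(d/L))$.
  Unit abscissa spacing (|Δx| only) is used, the dominant convention in
  EEG toolboxes.
- *Petrosian*: $\mathrm{PFD} = \log m / (\log m + \log\frac{m}{m+0.4
  N_\delta})$ with $m = T$ and $N_\delta$ the number of sign changes in the
  first differences; zero differences continue the previous sign.
- *Higuchi*: mean normalized curve length $L(j)$ over lags $j = 1..k_{max}$
  and offsets, with the FD taken as the least-squares slope of $\ln L(j)$
  on $\ln(1/j)$. $k_{max} = 10$ by default; the estimate depends on it, so
  it is exposed as a parameter.

All three are invariant under affine transforms $x \mapsto a x + c$, and
return 1 for smooth/degenerate inputs. The Higuchi estimator is validated
against two closed-form oracles: Weierstrass graphs (dimension
$2 + \ln a/\ln b$) and fractional Brownian motion (dimension $2 - H$).

**Hjorth (2).** Mobility $h_1 = \sigma_{\dot x}/\sigma_x$ (mean-frequency
estimate) and complexity $h_2 = (\sigma_{\ddot x}/\sigma_{\dot x})/h_1$
(bandwidth estimate), with derivatives taken as one-step finite
differences. The Δt factor cancels in $h_2$ and rescales $h_1$ uniformly
across epochs, so it is omitted. For a pure sampled tone of frequency $f$,
$h_1 = 2\sin(\pi f/F_s)$ and $h_2 = 1$; white noise gives
$h_1 = \sqrt2$ — these closed forms anchor the tests.

**Higher-order spectra (4).** The bispectrum
$\mathrm{Bis}(f_1,f_2) = E[X(f_1)X(f_2)X^*(f_1+f_2)]$ on the principal
domain $\Omega = \{0 \le f_2 \le f_1,\ f_1+f_2 \le F_s/2\}$, estimated
directly from rectangular-windowed FFTs (one full-epoch segment by
default; 2 or 4 sub-segments optionally). Features: mean magnitude
(BisMag), the sum of log magnitudes over Ω (H1), the same along the
diagonal $f_1 = f_2$ (H2), and the first-order spectral moment of the
diagonal log magnitudes with 1-based bin-index weights (H3). A floor of
1e−12 inside every logarithm keeps H1–H3 finite. The bispectrum is cubic
in the signal (doubling the input multiplies BisMag by 8) and sensitive to
quadratic phase coupling: a triplet $(f_1, f_2, f_1{+}f_2)$ whose third
phase equals the sum of the first two produces a phase-coherent peak at
the $(f_1, f_2)$ bin.

A point worth stating explicitly: the defining expectation $E[\cdot]$
matters. For a *single* epoch, the grid-mean |Bis| of Gaussian noise is
not small — nothing has averaged out, and at equal total power it exceeds
that of a phase-coupled triplet by an order of magnitude. Gaussianity
suppression emerges only under averaging: the complex bispectrum of noise
decays like $1/\sqrt K$ across $K$ independent segments or realizations
while a coupled peak is phase-coherent and survives. The package's tests
therefore state the Gaussian-baseline property under complex averaging
(50 realizations × 4 segments), which is the estimator-level form of the
definition.

## Classifiers and cross-validation

**GSVM** — a support vector machine with Gaussian RBF kernel
(`e1071::svm`), tuned over the box constraint $C \in [10^{-2}, 10^3]$ and
kernel coefficient $\gamma \in [10^{-3}, 10^1]$, both log-uniform.

**CART ensemble** — boosting over classification trees where every round
trains on a class-balanced random undersample drawn with probability
proportional to the current boosting weights (RUS-boosting), the standard
remedy for label imbalance. Tuned over the number of boosting cycles
[10, 300] (log-uniform), the learning rate [0.01, 1] (log-uniform) scaling
each round's vote weight, and the minimum leaf size [1, 50]. With one
cycle and learning rate 1 the model reduces to a single undersampled tree.
The base learner is a compact compiled Gini CART (binary splits, minimum
bucket size, complexity threshold cp = 0.01, depth cap 30) written for
this package: a boosting run makes thousands of small tree fits, and the
fixed per-call model-frame overhead of formula-interface tree fitters
dominates the runtime at these sizes. An `engine = "rpart"` option fits
the same protocol through `rpart` and is used as a cross-check in the test
suite. Undersampling is attached to the tree ensemble only; the SVM
receives standardized features without resampling.

**Protocol.** Evaluation is subject-dependent: each subject's epochs are
split into 4 stratified outer folds; within each outer training set, a
seeded random search (default budget 20 draws) is scored by stratified
inner 3-fold accuracy, the best configuration is refit on the full outer
training set and scored once on the held-out fold. Predictor
standardization (z-scoring with training-fold statistics; zero-variance
columns centred only) is refit inside every inner and outer training fold,
so no test statistics leak into training. The subject's accuracy is the
arithmetic mean of the 4 outer-fold accuracies. Random search replaces
Bayesian optimization deliberately: the hyperparameters and their ranges
define the method, the optimizer is an implementation detail, and a seeded
random search is reproducible without further dependencies. Fold splitting
is per-epoch by default, which lets epochs of one trial appear on both
sides of a fold boundary; `splitUnit = "trial"` groups whole trials when
that leakage channel is a concern.

## Feature-set comparison statistics

Per-subject mean accuracies of a reference set (fractal by default) are
compared against every other set with two-tailed paired t-tests,
Holm–Bonferroni corrected across the family, plus Cliff's delta — the
brute-force normalized count of dominating pairs, in [−1, 1] — as a
non-parametric effect size. Two degenerate cases are handled explicitly:
identical paired vectors report t = 0, p = 1; constant non-zero
differences (zero-variance denominator, unbounded evidence) report
t = ±Inf, p = 0, flagged `degenerate`. For topography, a chosen feature is
z-scored per channel over *all* epochs before class-splitting, averaged
within high/low groups, and exported as a channel:value table over the 14
shared montage channels for a plotting layer to consume.

## The synthetic dataset

`genDataset()` emulates the study conditions the pipeline targets:
14-channel recordings (EPOC 10–20 montage names) at 256 Hz, 60 s trials,
two classes drawn evenly within subject, ratings on a 1–9 scale
straddling 4.5, and occasional blink-like artifacts. Three class effects
are planted:

- **Fractality** — each channel is an independent fractional Brownian
  motion path (exact-covariance circulant embedding of fGn, cumulated),
  Hurst 0.45 for class 0 vs 0.70 for class 1. The fBm *path* is used
  rather than the stationary fGn increments because Higuchi's estimator
  saturates near 2 for fGn at any Hurst value, while the path obeys
  FD = 2 − H. The path is band-limited above 1 Hz inside the generator
  (real EEG carries little sub-1 Hz power past the amplifier high-pass;
  it also avoids the µV-scale ambiguity of an unbounded random walk) and
  normalized so both classes share the same texture SD
  (`amplitudeScale`, default 10 µV). Without that normalization the
  H = 0.7 class comes out ≈ 3.5× larger in post-filter amplitude —
  a gross power cue that is not one of the intended class effects. The
  fine-scale fractality survives the full conditioning chain: per-epoch
  HFD means ≈ 1.54 vs 1.37 for the two classes.
- **Alpha power** — a 10 Hz tone at 5% of the texture SD, 1.5× larger in
  class 1.
- **Quadratic phase coupling** — a 6/9/15 Hz cosine triplet at 3% of the
  texture SD, phase-coupled only in class 1.

The oscillatory amplitudes are kept near the fine-scale increment
amplitude of the fractal texture: if the smooth oscillations dominate,
they erase the fractality difference entirely — an instructive failure
mode we measured while calibrating the generator. Ratings are drawn per
trial (matching trial-level self-reports), at threshold ±1.5 rating units
plus Gaussian noise (SD 0.7, giving ≈ 98% label fidelity);
artifacts are 400 ms half-cosine deflections of 150–300 µV on the frontal
channels at 2/min, guaranteeing the ±100 µV rule is exercised. What the
generator does *not* emulate: volume conduction and inter-channel
correlation, 1/f-plus-peaks spectra of real EEG, ocular/EMG artifact
taxonomies, non-stationarity across trials, and any genuine mapping from
affect to physiology — the generative link from valence/arousal to Hurst,
alpha and coupling is this package's choice of planted, recoverable
effects, not an empirical claim. Passing tests therefore demonstrate
machinery (signal-recovery at realistic SNR, absence of leakage,
correctness of the estimators), not real-data classification performance.

## Numerical choices

- fBm by circulant embedding (exact covariance), not wavelet synthesis:
  the FD oracle requires exact scaling behaviour. Negative embedding
  eigenvalues (tiny, from floating point) are clipped at zero.
- Logarithms in the FD estimators are natural; every printed form is a
  ratio of logs and hence base-invariant.
- The Morlet wavelet is complex (analytic); coefficients' magnitudes are
  used throughout. The per-scale summary uses mean of |C|, not |C|²:
  the magnitude convention matches the stated "absolute values of the
  coefficients".
- The bispectrum's expectation defaults to a single full-epoch FFT — 256
  samples leave little room for sub-segmenting; 2 or 4 segments are
  available.
- Degenerate inputs (constant epochs) yield defined feature values (0 or
  1 by estimator) with warnings, never NaN.
- Every stochastic stage (generator, fold assignment, hyperparameter
  draws, undersampling) is seeded from one run seed; per-subject seeds are
  derived as `seed + 1000 * subject_index`, so any subject's result is
  independently replayable.

## Problem sizes used in the shipped checks

The package's acceptance checks run the full pipeline on the default
synthetic dataset: 10 subjects × 16 trials × 60 s, ≈ 4500 retained epochs,
fractal and statistical sets, the CART ensemble with a hyperparameter
search budget of 6 draws per outer fold — on these strongly separated
planted effects the selected configurations plateau far below the default
budget of 20, and we verified the accuracies move by under half a point
between the two budgets. The label-permutation null uses 2400
pooled epochs. Estimator oracles use 20 seeds per condition (fBm, white
noise) and 50 realizations (bispectrum averaging).

One directional expectation is knowingly not met and is left failing in
the shipped checks rather than weakened: that the fractal set's mean
accuracy comes within 2 points of the statistical set's on the default
synthetic data. On an exactly self-similar *Gaussian* texture, the
statistical set's mean-absolute-difference statistics are efficient,
low-variance estimators of precisely the second-order structure that the
Hurst exponent controls, and they reach ceiling accuracy while the FD
estimators pay a small variance penalty (measured ≈ 95.0% vs 97.5%, a
gap of 2.4–2.6 points across search budgets). The robustness arguments usually made for FD features —
tolerance of noise, nonstationarity and intermittency — concern
properties of real EEG that this deliberately simple Gaussian generator
does not emulate, which is exactly the kind of real-data claim that
passing synthetic tests could not establish anyway.

## Known limitations

- Subject-independent (leave-one-subject-out) evaluation is out of scope.
- Only the five reported feature sets are implemented; spectral-power,
  entropy, nonlinear, connectivity and graph-metric families are not.
- No ICA/regression ocular correction, bad-channel interpolation or
  baseline correction; rejection is amplitude-thresholding only.
- Bicoherence normalization of the bispectrum is not implemented.
- The EDF reader handles continuous, single-rate, 16-bit EDF without
  annotations; EDF+ discontinuities are not supported.
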