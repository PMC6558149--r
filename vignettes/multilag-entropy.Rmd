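---
title: "Multi-lag symbolic entropy analysis of EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-lag symbolic entropy analysis of EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordlag)
```

`ordlag` measures how predictable a brain signal is at different time scales,
and uses that to tell a calm affective state from a distressed one. This
vignette explains the model behind each stage, the parameters that matter, the
synthetic data used to validate the pipeline, and the choices made where the
methodology left room.

## Ordinal patterns and the entropy family

A time series $x(1), \dots, x(N)$ is embedded into vectors of $m$ samples
taken $\tau$ apart, $X_i = (x(i), x(i+\tau), \dots, x(i+(m-1)\tau))$, giving
$N-(m-1)\tau$ vectors. Each vector is reduced to its *ordinal pattern*: the
permutation that sorts its samples. Amplitudes are discarded; only the rank
order survives, which makes the description robust to noise, drift and any
strictly increasing distortion of the signal. With pattern probabilities
$p(\pi_k)$ over the $m!$ possible patterns:

* **Permutation entropy (PE)** is the normalised Shannon entropy
  $-\sum_k p \ln p \,/\, \ln(m!)$ — 0 for a perfectly repetitive signal,
  1 when every pattern is equally common.
* **Amplitude-aware PE** re-weights each vector's contribution by
  $K \cdot AA + (1-K) \cdot RA$, where $AA$ is the vector's mean absolute
  amplitude and $RA$ its mean absolute successive difference; $K \in [0,1]$
  balances the two (default $K = 0.5$, an even balance). Evaluated across
  embedding delays this is called **delayed permutation entropy (DPE)**.
* **Rényi permutation entropy (RPE)** generalises PE with a bias order $q$:
  $q<1$ emphasises rare patterns, $q>1$ frequent ones.
* **Permutation min-entropy (PME)** is the $q \to \infty$ limit,
  $-\ln \max_k p(\pi_k) / \ln(m!)$: it sees only the single most probable
  pattern, which makes it unusually sensitive to a weak periodic structure
  hiding under broadband activity.

PME is defined on the plain relative-frequency distribution. No
amplitude-weighted min-entropy is offered: the min-entropy limit is derived
from the unweighted Rényi family, and extending it to weighted probabilities
would be a new estimator with no established interpretation, so the package
rejects weighted input rather than guessing.

The embedding delay $\tau$ acts as a time-scale dial. At $\tau = 1$ patterns
describe sample-to-sample microstructure; at $\tau = 10$ (with $m = 6$ and
128 Hz sampling, a window of about 0.4 s) they describe slower rhythms. A
process whose class difference lives in a slow rhythm can therefore look
identical at $\tau = 1$ and separate cleanly at $\tau = 9$ — the core
motivation for sweeping lags rather than fixing $\tau = 1$.

```{r curves, fig.width = 6, fig.height = 3}
x <- rnorm(2000)
plot_entropy_curves(entropy_curve(x, m = 4, taus = 1:10))
```

### Numerical conventions

* Ties between equal samples are broken by temporal order (earlier index
  ranks lower) — the standard ordinal-analysis convention. It is
  deterministic and preserves monotone invariance; an all-constant series
  maps to the ascending pattern with entropy 0, not an error.
* Patterns are encoded by the Lehmer code of the sorting permutation, a
  bijection onto $1..m!$ computed in $O(m^2)$ per vector in compiled code.
* $0 \ln 0 = 0$ throughout; logarithms are natural; every entropy is
  normalised by $\ln(m!)$ into $[0, 1]$.
* With $m = 6$ and 30 s of 128 Hz signal there are at most 3795 vectors for
  720 patterns — about a 5-fold coverage. Entropies at $m = 6$ are therefore
  biased low in absolute terms. No undersampling correction is applied; the
  analysis compares groups under identical conditions, where the shared bias
  cancels at first order. This is a known caveat when comparing absolute
  values across different $(m, N)$.
* `m` is capped at 10 ($10! \approx 3.6$M pattern bins); beyond that the
  distribution no longer fits sensibly in memory and could never be sampled.

## Multi-lag curve features

DPE and PME are computed at $\tau = 1..10$ ($\tau_{max}$ is a parameter;
10 is the default), giving one curve per channel per metric. Each curve is
parameterised into 21 features:

* the 10 single-lag entropies `tau1..tau10`;
* 5 slopes `Slp1-2 .. Slp1-10`: the slope of the straight line from
  $(1, E[1])$ to $(\tau, E[\tau])$ for $\tau \in \{2,4,6,8,10\}$, i.e.
  $(E[\tau]-E[1])/(\tau-1)$;
* 5 areas `Ar1-2 .. Ar1-10`: the composite trapezoidal area under the curve
  over the same segments, on a unit-spaced lag axis — the simplest quadrature
  consistent with treating the curve as piecewise linear, matching the
  straight-line reading used for the slopes;
* the arc length `AL` $= \sum_{\tau=2}^{10}\sqrt{1+(E[\tau]-E[\tau-1])^2}$,
  taken verbatim with unit lag steps and unnormalised entropy differences,
  so a flat curve scores exactly 9 and every deviation adds length.

Feature names follow `channel/metric/feature` (e.g. `P3/PME/Slp1-4`) and are
stable across runs; a 32-channel montage yields $21 \times 2 \times 32 =
1344$ features per trial.

## Preprocessing

The cleaning order is fixed: downsample to 128 Hz → common-average
re-reference → zero-phase band limiting (3–45 Hz) → noisy-channel *detection*
→ independent-component artifact removal → noisy-channel *interpolation*.
Detection happens before the component arithmetic so the statistic is
measured on unmixed data, but replacement waits until after it, so the
interpolation's smoothing never contaminates the decomposition.

Filters are 4th-order Butterworth sections applied forward and backward
(`signal::filtfilt`), giving zero phase and a doubled effective order. The
cutoffs keep the physiological bands of interest while removing baseline
drift and line interference.

The decomposition itself is delegated to FastICA (`ica::icafast`, logcosh
contrast), with the component count defaulting to the numerical rank of the
channel covariance — after common-average referencing the data lose one rank,
and decomposing at full channel count would blow up the null dimension.
Five statistics are computed per component: maximum absolute correlation with
the EOG traces, spatial kurtosis of the scalp map, the slope of the log power
spectrum over 8–45 Hz, the Hurst exponent, and the median absolute gradient
of the activation. Each is standardised across components and a component is
removed when any statistic deviates more than 3 SD from the component mean.
Two details deserve note:

* a criterion with zero spread flags nothing (the z-score is undefined and
  the criterion carries no information);
* with $n$ components the largest attainable z-score is $(n-1)/\sqrt{n}$, so
  the 3-SD rule is structurally inert below about 12 components. This is a
  property of the rule itself, not of this implementation; it is why the
  package's own validation uses montages of 16 or more channels.

The spectral slope is a linear fit of log-power against log-frequency over
8–45 Hz (below the low-pass edge); the Hurst exponent comes from detrended
fluctuation analysis with log-spaced window sizes between 4 samples and
$N/4$. Both are reasonable, widely used readings of criteria that are
conventionally named but not formally defined.

Noisy channels are flagged by robust z-scores (median/MAD) of the log
channel variance (one-sided, only high amplitude counts) and of the channel
Hurst exponent. Because the MAD of a small montage can be arbitrarily small,
each criterion additionally requires a minimal raw effect (a doubling of
variance, or a Hurst deviation of 0.15) — without the floor, an 8-channel
montage over-flags ordinary channels. If more than 25% of channels are bad
the trial aborts with a quality error rather than pretending interpolation
can fix it. Flagged channels are replaced by the inverse-distance-weighted
average of their 3 nearest montage neighbours on the projected 2D head
layout.

## The synthetic study

Real affect-labelled EEG requires a gated download, so validation runs on a
synthetic generator that reproduces the *statistical structure* the analysis
assumes, at the study's scale: 122 "distress" and 137 "calmness" trials,
30 s at 128 Hz, up to 32 channels with 10–20 labels, each trial carrying
self-assessment ratings drawn inside its class's arousal/valence region
(distress: arousal > 5 and valence < 3; calmness: arousal < 4 and valence in
[4, 6]; ratings are drawn continuously inside the open region — rounding to
integer scale points could cross the strict boundaries, and every generated
rating must re-derive its own label).

Each channel is an AR(2) process with complex poles at 10 Hz plus an explicit
10 Hz sinusoid and white sensor noise. The distress class has a stronger pole
(0.88 vs 0.78) and larger oscillation (1.2 vs 0.8): its dynamics are more
repetitive, so its ordinal patterns concentrate and every entropy drops —
the qualitative signature of interest (calm cortical activity is the more
irregular one). Crucially, the class parameters are jittered at two levels:

* a *trial-level* jitter (pole SD 0.035, oscillation SD 0.25) shared by all
  channels of a trial, modelling subject/state variability — this makes the
  classes genuinely overlap, so no single feature is perfect;
* a *channel-level* jitter (pole SD 0.05, oscillation SD 0.15) independent
  across channels — this noise averages out across the montage, which is
  exactly why a multivariate classifier can beat the best single feature.

These values were chosen once, when the generator was designed, to place the
single-feature accuracy in a realistic 80–90% band with a visible
multivariate margin; they are not fitted to any particular outcome. A
separate scenario (`lag_contrast_scenario()`) gives both classes identical
fast dynamics and hands the distress class only a slow 3 Hz rhythm
(amplitude 2 by default): over a lag-1 window the slow rhythm is nearly
constant and the classes are indistinguishable, while at lag 9 the window
spans a good part of the slow cycle and the distress patterns become
markedly more regular — the class difference emerges only at long delays.

What the generator does *not* emulate: volume conduction and realistic scalp
topography, 1/f background spectra, non-stationary artifacts beyond stylised
blinks and electrode pops, inter-subject structure (trials are exchangeable,
so only trial-wise cross-validation is meaningful), and any actual
physiology of affect. Passing the synthetic validation shows the pipeline
recovers planted structure of the assumed kind; it is not evidence about
real recordings.

Everything is seeded: a dataset's manifest (config + master seed) regenerates
it bit-identically, with per-trial seeds derived from the master seed.

## Evaluation

Features are screened with Shapiro–Wilk, Levene (mean-centred) and one-way
ANOVA per feature; the distributional tests are advisory and the ANOVA
p-values are reported raw (Benjamini–Hochberg adjustment is available but
off by default, mirroring the per-channel testing convention this analysis
follows).

Discrimination is estimated with stratified 10-fold cross-validation: fold
sizes differ by at most one trial and class composition per fold is within
one trial of the global proportions (each class's remainder trials go to the
currently smallest folds; shuffling is seeded). For a single feature, the
classifier is a ROC threshold fitted on the nine training folds: every
midpoint between consecutive sorted unique training values (plus the two
infinite cuts) and both polarities are scanned, and the cut maximising
training accuracy wins. Ties are resolved by larger sensitivity +
specificity, then smaller threshold, then the "high values mean distress"
polarity — deterministic, and favouring balanced errors. Distress is the
positive class throughout; sensitivity is the distress detection rate. A
fold whose test set happens to contain one class yields an undefined rate,
reported as missing and excluded from that rate's average with a warning.

Four multivariate classifiers are provided with the study's settings: a
Gini-split decision tree that stops splitting nodes holding fewer than 20%
of the training trials; a cubic-polynomial-kernel SVM with kernel scale and
cost 1; quadratic discriminant analysis (with a diagonal-ridge fallback when
a class covariance is singular, logged); and a 10-nearest-neighbour vote
weighted by squared inverse Euclidean distance. The KNN standardises
features on training statistics by default — with features as differently
scaled as `tau1` (≈0.9 ± 0.02) and `Ar1-10` (≈8), unstandardised Euclidean
distance reduces to the largest-scale feature. The SVM is left on raw
features to keep the literal "kernel scale 1" reading.

Feature subsets come from sequential forward selection nested *inside* each
outer fold: candidates are scored by misclassification under a stratified
10-fold CV of the outer training set, the best feature is added while it
strictly improves, up to a cap of 10. Ties go to the earliest column, so a
duplicated feature can never be selected twice. The selected set is refitted
on the full outer training data and scored once on the held-out fold;
selection counts across folds are reported. Test folds are never visible to
any fitting step, including threshold choice and selection.

## Problem sizes used in the package's own validation

The bundled tests exercise the full study geometry where it matters
(259 trials; 122/137 split; 30 s at 128 Hz) with 8-channel montages for the
classification experiments and 16 channels for the IC-scoring experiments
(see the z-score ceiling above), 5 seeds for the recovery experiment and
50 runs for the artifact-flagging rates. These sizes were chosen as the
smallest that make the measured quantities stable; the generator and
pipeline run unchanged at 32 channels.

## Known limitations

* Entropy values at $m = 6$ are undersampling-biased; compare only within a
  fixed $(m, N, \tau)$ setting.
* The IC artifact rule is inert on small montages (see above) and, like any
  z-score rule, assumes most components are clean.
* The greedy selection is a heuristic; it reports occurrence counts, not
  importances, and different seeds can select different near-equivalent
  features (which the counts make visible).
* The synthetic validation bounds what can be claimed about real EEG; see
  the generator section.
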