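---
title: "Acoustic diagnosis of pulmonary hypertension: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic diagnosis of pulmonary hypertension: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonoPH)
```

## The diagnostic model

Pulmonary hypertension (PH) — mean pulmonary artery pressure (mPAp)
≥ 25 mmHg — alters the second heart sound: the pulmonary valve-closure
component P2 becomes louder relative to the aortic component A2, and the
A2–P2 splitting interval widens. `phonoPH` treats the diagnosis as a
two-class audio-classification problem in the style of speaker
recognition: compact spectral-shape features (MFCCs) of the S2 sound,
one generative model (a Gaussian mixture) per class, and a
likelihood-ratio-like decision.

A subject's feature matrix \(X = (x_1, \dots, x_N)\), with one row per
20 ms analysis frame, is scored under each class mixture by the
frame-averaged negative log-likelihood

\[
\mathrm{NLL}_c(X) = -\frac{1}{N} \sum_{i=1}^{N}
  \log \sum_{k=1}^{K} w_k^{(c)}\,
  \mathcal{N}\!\left(x_i;\, \mu_k^{(c)}, \Sigma_k^{(c)}\right),
\]

and predicted to the class with the lower NLL. Averaging per-frame
*log*-likelihoods (rather than likelihoods before the log) is assumed:
it is the standard choice, is numerically stable, and makes the
statistic independent of N, so recordings of different lengths are
comparable. The ratio \(\mathrm{NLL}_{PH} / \mathrm{NLL}_{non\text-PH}\)
is the reported test statistic: values below 1 favor PH. Sweeping a
threshold over this ratio yields the ROC curve.

## Segmentation: finding S2 with the ECG

The ECG anchors the cardiac cycle. Since no specific detector is
prescribed by the approach this package implements, the choices below
are standard and documented here as this package's own:

* **R waves** — a Pan-Tompkins-style chain: 5–25 Hz band-pass
  (2nd-order Butterworth, zero-phase), first difference, squaring, and a
  150 ms moving-window integration. The threshold is a configurable
  multiple (default 4) of the running median of the detection function
  over a 2.5 s window; candidates below 20 % of the candidates' upper
  amplitude quantile are discarded (T waves leak through the band-pass
  at slow heart rates), a 200 ms refractory period is enforced, and each
  detection is refined to the peak of the 50 ms-smoothed band-passed
  energy, which centers it on the biphasic QRS deflection.
* **T waves** — the maximum of the 10 Hz low-passed ECG in the window
  \((r + 0.12\,\mathrm{s},\; r + 0.55\,RR)\), one per complete RR
  interval. The window avoids the QRS and the following cycle.
* **S2 window** — 30 % of the cycle, centered on the T wave (the
  centering is an assumption; at 72 bpm this is the classic 0.25 s
  window). The S2 center is the maximum of the short-time energy — a
  20 ms moving average of the squared 25–150 Hz band-passed PCG — inside
  the window, and a 100 ms snippet centered there is extracted. 100 ms
  covers A2 plus P2 at the widest simulated split (60 ms) and yields 9
  frames at the 20 ms / 10 ms framing; snippets that would overrun the
  recording are dropped and counted.

Times are seconds from recording start; intervals are half-open
`[start, end)`; `sample index = round(time × rate) + 1`.

## MFCC features

Defaults: 20 ms frames, 10 ms hop (50 % overlap), pre-emphasis 0.97,
Hamming window, FFT at the next power of two above the frame length, 26
triangular mel filters spanning 0 to Nyquist with centers equally spaced
on mel(f) = 2595·log₁₀(1 + f/700), natural log with a floor at 10⁻¹²
times the frame's largest filter energy (10⁻³⁰ absolute for silent
frames), an *orthonormal* DCT-II, and the first 13 coefficients
(indices 0–12, so the energy-like 0th is included — the usual
audio-processing reading of "first 13"). No liftering and no delta
coefficients are applied. A 25 ms frame length is an equally defensible
reading of the source material's figure caption; both are supported and
20 ms (the body-text value) is the default.

Under the orthonormal DCT the coefficients are reproducible across
implementations: scaling a frame by \(c\) shifts only coefficient 0, by
\(2\sqrt{M}\log c\) for \(M\) filters, leaving 1–12 unchanged — a
property the test suite asserts, alongside bitwise-level agreement with
a direct-summation DFT + explicit cosine-sum oracle.

## Mixture fitting

Each class model has K = 8 components (the model order used for this
classifier) with full covariances; a diagonal mode is available for
small cohorts. EM details:

* k-means initialization with seeded starts; 3 independent restarts,
  keeping the best final log-likelihood; deterministic given the seed.
* E-step responsibilities in log space via log-sum-exp.
* A 10⁻⁶ ridge added to every covariance diagonal at each M-step;
  a component whose effective weight collapses below identifiability is
  re-seeded at a random observation with the global covariance (and a
  warning).
* Convergence at relative log-likelihood improvement < 10⁻⁶, capped at
  200 iterations. The per-iteration log-likelihood trace is stored and
  is non-decreasing (the EM guarantee; asserted with 10⁻⁹ slack to
  absorb the ridge).
* A fit requires N ≥ K(D+1) frames — below that the error suggests
  fewer components.

Exact NLL ties are resolved to non-PH: for a screening tool a false
negative merely defers to existing practice, while the conservative tie
break avoids manufacturing positives from numerically identical scores.

The density kernels (per-component log densities and weighted
covariance accumulation) are compiled (RcppArmadillo), which keeps the
full cross-validated study at interactive speed.

## Evaluation design

Cross-validation is at the **subject** level: all frames of a subject
stay on one side of the train/test split, and a structural assertion in
the CV loop verifies that no scored subject contributed frames to the
models that scored it. Folds are stratified by class by default —
plain random partitioning can orphan a class in a small training fold —
with an unstratified flag for fidelity to simple random splitting;
class remainders are placed on the smallest folds so overall sizes
differ by at most one. When mPAp is available, each fold logs a Welch
t-test p-value comparing train and test pressures.

Pooled (micro-averaged) confusion counts are the primary summary and
the per-fold macro-average is also reported, since "averaging the
iterations" admits both readings. Rates with zero denominators are
reported as undefined (`NA`), never as 0. The ROC sweeps the observed
NLL ratios plus ±∞ endpoints, treats tied scores atomically, and
integrates by the trapezoidal rule; the suite cross-checks the AUC
against brute-force Mann–Whitney pair counting and an independent ROC
implementation. Reader comparisons use a chi-squared two-proportion
test per rate (correct rate, FNR, FPR) — this package's choice, not a
claim about how the original physician comparison was computed.

## The synthetic cohort simulator

The simulator exists so the full pipeline is testable with ground truth
and no data download. Per cardiac cycle it renders:

* an ECG with a sharp biphasic R deflection (derivative-of-Gaussian,
  σ = 10 ms) and a smooth T hump (σ = 40 ms, amplitude 0.35) at 32 % of
  the RR interval;
* a PCG with an S1 burst 55 ms after R, then an S2 made of two
  Gaussian-enveloped damped sinusoids: A2 (50 Hz, σ = 8 ms, unit
  amplitude) at the T peak and P2 (45 Hz, σ = 8 ms) delayed by
  `split_map(mpap)` and scaled by `p2_gain_map(mpap)`.

Defaults are chosen once as a plausible rendering of the physiology:
sampling rate 2000 Hz (heart sounds live well below 700 Hz), 20 s
recordings, heart rate 70 ± 10 bpm across subjects with 3 % lognormal
cycle-length jitter within subjects, additive Gaussian noise at 2 % of
each channel's peak, mPAp drawn uniformly from 28–54 mmHg (PH) and
10–24 mmHg (normal) — straddling the 25 mmHg diagnostic threshold with
class means near the cohorts the pipeline targets — and linear monotone
maps: split 20 ms at 15 mmHg → 60 ms at 60 mmHg, P2/A2 ratio 0.4 → 1.5
over the same range. Only the monotonicity of the maps matters to the
classifier; the slopes set the difficulty of the synthetic task.

The ground-truth S2-center annotation is the peak of the same
short-time-energy operator the segmentation stage uses, evaluated on
the *clean* (noise-free) signal — i.e. the noiseless value of exactly
the quantity the stage estimates. Per-subject child seeds derive from
the cohort seed, so cohorts are bit-reproducible and subjects
independent.

**What the simulator does not emulate** — and hence what passing tests
do not show about clinical data: realistic ECG morphology (P waves, QT
dynamics, arrhythmia), murmurs and ejection clicks, respiratory
splitting variation, sensor and contact noise, and the continuous,
overlapping relation between mPAp and acoustics in real patients. The
separated synthetic cohorts make the classification task easier than
the clinical one; the simulation results bound what the code can do,
not what the method achieves at the bedside.

## Problem sizes and numerical choices

The shipped studies use sizes chosen to exercise the full pipeline at
desk scale: a 40 + 40-subject discrimination study (5 seeds in the
acceptance suite), 24-subject identical-acoustics null cohorts (10
seeds), 20-seed Monte-Carlo R-detection runs at 10 % noise, and 5000
draws for mixture-recovery checks. Log floors, the covariance ridge,
and the log-sum-exp trick are the only numerical safeguards; all are
documented above with their defaults.

## Known limitations

* The ECG is required: there is no acoustic-only S2 detector.
* WAV I/O is 16-bit PCM with relative amplitudes; absolute calibration
  is neither stored nor used.
* The two-proportion reader comparison and the balance t-test are
  descriptive conveniences, not a re-derivation of any published
  p-value.
* Model-order selection is fixed at K = 8; a cross-validated sweep is
  possible through the configuration but not automated.
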