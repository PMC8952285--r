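---
title: "Cardiopulmonary resonance indices for sleep CAP analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiopulmonary resonance indices for sleep CAP analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`capcri` detects the cyclic alternating pattern (CAP) of sleep and screens
for insomnia and narcolepsy using cardiorespiratory signals only — no EEG.
This vignette is the package's own account of the science: the model behind
the resonance indices, the feature and classifier design, what the
synthetic-data generator does and does not emulate, and the numerical
choices a maintainer would want written down.

## 1. Respiratory sinus arrhythmia as directed coupling

During quiet sleep the vagal outflow modulates heart rate at the breathing
frequency (respiratory sinus arrhythmia, RSA). The depth and shape of that
modulation vary with sleep depth, with the A-phases of the cyclic
alternating pattern, and with pathology. The package quantifies RSA as
*directed* coupling: how much does the respiration signal's past improve
the prediction of the RR-interval series beyond the RR series' own past?

Both channels are modelled jointly as a bivariate autoregressive process of
order $p$ at 4 Hz,

$$
\mathrm{RRI}(t) = \sum_{j=1}^{p} A_{11,j}\,\mathrm{RRI}(t-j)
  + \sum_{j=1}^{p} A_{12,j}\,\mathrm{RSP}(t-j) + \varepsilon_1(t), \qquad
\mathrm{RSP}(t) = \sum_{j=1}^{p} A_{21,j}\,\mathrm{RRI}(t-j)
  + \sum_{j=1}^{p} A_{22,j}\,\mathrm{RSP}(t-j) + \varepsilon_2(t),
$$

fitted by ordinary least squares (`fit_bivar_ar()`). The time-domain
Granger measure is the log ratio of the restricted (own-lags-only) to the
unrestricted channel-1 prediction-error variance,
$G = \ln \mathrm{var}(\varepsilon_1^{R}) / \mathrm{var}(\varepsilon_1^{U})$,
which is non-negative by construction because the restricted least-squares
problem is nested in the full one. Its spectral decomposition (Geweke's
measure, `gc_spectrum()`) attributes the coupling across frequency through
the fitted transfer function after rotating away the residual correlation;
its average over the full Nyquist band recovers the time-domain value — a
property the test suite checks against numerical quadrature on simulated
unidirectional processes.

## 2. The resonance indices

The curve $G(f)$ over the respiratory band (0.03–0.5 Hz) is summarised by
the cardiopulmonary resonance indices (`extract_cri()`), in the language of
a series resonant circuit in which the lungs and heart exchange energy and
non-respiratory influences act as damping:

* $F_A$ — resonance frequency: the argmax of $G(f)$ in the band;
* CRA — resonance amplitude $G(F_A)$, the coupling depth;
* CRB — bandwidth: full width of $G(f)$ at half maximum, by linear
  interpolation between grid points;
* CRQ $= F_A/\mathrm{CRB}$ — the quality factor of the resonance;
* CRR $= \mathrm{CRB}/(2\pi F_A^2)$ — the resonance resistance (damping
  analogue), under the convention that the capacitance is normalised to 1.

These definitions satisfy the identity
$\mathrm{CRQ}\cdot\mathrm{CRR}\cdot 2\pi F_A = 1$ for every emitted record,
which the tests assert. The circuit reading makes CRR increase with
damping: groups with weak, broad coupling (narcolepsy-like) show high CRR,
groups with rigid, narrow-band coupling (insomnia-like) show high CRQ and
low CRR. Whether $G(f)$ should be normalised before peak extraction is not
settled; raw values are used, so CRA is on the natural log-ratio scale.

Indices are computed on 120-s windows every 10 s (`cri_track()`). Windows
whose raw respiration fails the quality gate $Q > 0.85$ — $Q$ being the
fraction of power-spectral-density mass inside 0.03–0.5 Hz
(`respiration_quality()`) — are kept in place as missing records so the
grid stays regular.

## 3. Preprocessing

* **Baseline and noise.** Baseline drift is removed by zeroing the
  approximation branch of a db4 discrete wavelet decomposition (level
  chosen so the approximation band lies below the low band edge); residual
  out-of-band noise by zero-phase Butterworth filters (order 2 high-pass at
  the low edge — low normalised cutoffs are numerically fragile at higher
  order in transfer-function form — and order 4 low-pass at the high edge;
  forward–backward application preserves phase and doubles the effective
  order). `cri_track()` band-passes the respiration channel to the
  respiratory band before modelling; the quality gate always sees the raw
  signal.
* **Beat detection** (`detect_r_peaks()`) uses the classic
  derivative–square–integrate scheme with an adaptive threshold, a 250-ms
  refractory period and refinement to the local extremum of the band-passed
  ECG; simulator ground truth puts recall and precision above 99% at
  ±20 ms.
* **RR cleaning** (`clean_rr()`) flags an interval when it deviates from
  the running series mean (61-beat centred moving average) by more than
  1.5 segment standard deviations, or falls outside 0.7–1.3 times the
  previous accepted interval, and replaces flagged intervals by natural
  cubic interpolation through the valid neighbours. Two properties of this
  rule are worth stating plainly. First, the 1.5-SD gate is
  self-referential: any noisy series regrows a ~1.5-sigma tail after
  trimming, so re-estimating the gate and iterating would progressively
  flatten genuine variability rather than converge; the gates are therefore
  computed once per segment, and exact idempotence holds in the regime the
  rule is meant for (isolated ectopic or missed beats on an otherwise
  regular tachogram). Second, the statistics must be *local*:
  `clean_rr_segmented()` (the pipeline default, 5-minute segments) exists
  because whole-night statistics would treat the baseline difference
  between sleep stages — which exceeds 1.5 SD — as artefact and clip entire
  stages.
* **Windowing** follows the `floor((T - 120)/10) + 1` rule
  (`sliding_windows()`), truncating partial windows.

## 4. Features per 30-s epoch

Twenty-one features (`cap_feature_names("base")`): 3 body-movement
(variance, approximate entropy, sample entropy of the vector-magnitude
acceleration — magnitude makes the three numbers rotation invariant and
keeps the count at 3), 12 HRV (SDNN, RMSSD, pNN50; VLF/LF/HF power and
LF/HF with VLF 0.003–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz on the 4-Hz
resampled tachogram; Poincaré SD1, SD2, SD1/SD2; sample and approximate
entropy, $m=2$, $r=0.2\,\mathrm{SD}$) and 6 resonance features (CRA, CRB,
CRQ, CRR plus the variance and 10-bin Shannon entropy of CRA over a 5-min
context, bins fixed per subject between the 1st and 99th CRA percentiles).

Two design points: HRV and the resonance features are supported by a 120-s
window centred on the epoch — spectral HRV is not estimable on 30 s — and
stamped to the 30-s grid; SDNN uses the population normalisation so that
SD1 $=$ RMSSD$/\sqrt2$ and SD1² + SD2² = 2 SDNN² hold exactly. Missing
values (failed quality gate, too few beats) are encoded as NA, never as
silent zeros; the classifier imputes per-class training medians.

## 5. Stability features, staging and diagnosis

A supervised 18-state hidden Markov model (`train_hmm()`) over the CRA
sequence — states are the canonical labels W, REM, and {non-A, A1, A2, A3}
within each of S1–S4 — estimates the transition matrix by bigram counting
and per-state Gaussian emissions. For each epoch, Viterbi decoding of the
CRA sequence yields a state whose transition-matrix diagonal entry and
column sum are appended as characteristics 22 and 23: how self-persistent
the decoded state is, and how strongly the chain flows into it. Unlabelled
rows (states never visited in training) are set uniform and flagged.

Staging is a two-layer random forest (`train_stager()`, 500 trees,
$\sqrt d$ features per split, inverse-frequency class weights, fixed seed):
layer 1 predicts the six macro stages; epochs predicted S1–S4 go to that
stage's layer-2 forest for the CAP phase. Layer-1 training keeps only
epochs inside runs of ≥ 20 identical WAKE/LIGHT/DEEP macro labels (10
minutes of stable stage; REM epochs, which the run rule does not cover, are
all kept), while the phase layers use every labelled epoch. Feature
outliers beyond median ± 5 MAD (training statistics) are winsorised after
an optional re-preprocessing callback (`compensate_outliers()`).

Diagnosis is subject-level: `summarize_subject()` builds an
epoch-order-free summary (per-macro-stage means and variances of the 23
characteristics, the deep-sleep CRA/CRB/CRQ/CRR profile, and the A-vs-NA
CRA contrast per stage and pooled), and an RBF support-vector machine
(`train_diagnoser()`, standardized inputs, small inner 3-fold grid over
cost and kernel width) separates healthy / insomnia / narcolepsy. A
subject-level decision — not per epoch — is the only meaningful unit for a
chronic condition. Confirmed cases are appended to a versioned training
library (`update_library()`); retraining is always explicit.

## 6. The synthetic-data generator

`simulate_cohort()` generates full nights that have exactly the structure
the method assumes, so every stage of the pipeline is testable without
external recordings:

* **Hypnogram**: an 18-state Markov chain shaped like adult sleep
  architecture — long non-A runs, mostly single-epoch A-phases recurring
  within about a minute during CAP sequences, graded stage transitions,
  arousals more likely from A3 (`default_transition_matrix()`).
* **Respiration**: a stochastic narrow-band AR(2) resonator at the
  profile's respiratory frequency, plus sensor noise (SNR 20–26 dB,
  typical of effort belts). The resonator — not a drifting sinusoid — is
  essential: breathing must carry breath-to-breath innovation for the
  causal direction to be identifiable at all; a deterministic oscillation
  is predictable from the RR channel's own history and would carry no
  incremental information.
* **RR intervals**: instantaneous RR = smoothed state baseline + state
  coupling gain × delayed respiration (0.5 s vagal latency) + AR(1)
  non-respiratory variability; beats are placed by integrate-and-fire on
  the instantaneous rate, so the tachogram genuinely carries the
  modulation and the meaning of CRA in simulation is exact.
* **Movement**: baseline accelerometer noise with short oscillatory bursts
  whose rate and amplitude depend on state (frequent/large in wake and A3,
  intermediate in A2, small in A1 — the graded somatomotor impact of the
  A subtypes).

**Group profiles** (`group_profile()`) encode the qualitative contrasts the
method exploits. Healthy: RSA gain deepening with NREM stage (1.5 ms in
wake to 8 ms in S4) and dropping during A-phases (A1 70%, A2 45%, A3 22% of
the stage gain), breathing at 0.25 Hz with 0.05 Hz bandwidth. Insomnia
(hyperarousal): elevated nocturnal heart rate (baseline RR 120 ms shorter),
rigid slightly faster breathing (0.26 Hz, 0.025 Hz bandwidth — hence high
CRQ and low CRR), high non-A coupling in deep sleep (18–22 ms) with a
strong A/NA swing (A-phase gains 8–25% of non-A). Narcolepsy: globally low
gains (1–5 ms), noisier non-respiratory variability, slower breathing
(0.21 Hz) — low CRA and CRB, high damping.

Two calibration facts shaped the gain scale, measured on single-state
recordings before the end-to-end experiments were run: the realized
post-pipeline CRA saturates (around 3 on the log scale) because Eq.-style
RR cleaning necessarily replaces ~10% of beats at breath extremes and the
integrate-and-fire beat sampling is nonlinear at large modulation depth;
and very narrow-band breathing is attenuated further by the AR model's
resolution at $T = 480$. Gains therefore sit in the regime where the
estimate responds monotonically (the tests check strict monotonicity of
median CRA over gains 0/3/6/12/24), and the insomnia contrast is carried by
the full hyperarousal picture (gain *and* heart rate *and* breathing
rigidity) rather than by gain alone.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: ECG morphology beyond a Gaussian R-wave template
(no ectopy, no arrhythmia, no electrode artefacts), apnoea, periodic limb
movements, the EEG ground truth itself (labels are the simulator's own
states, not expert CAP scoring), inter-scorer disagreement, and real
inter-subject variability beyond log-normal gain and baseline shifts. The
acceptance-level end-to-end figures are sanity bars on internal
consistency, not predictions of performance on polysomnography databases.

## 7. Numerical choices and degenerate inputs

* AR modelling rate 4 Hz (covers the band with margin), $T = 480$ per
  window; order by BIC over 1–12 (all candidates scored on the same
  effective sample), fixed order available via `order =`.
* Normal-equation solves carry a $10^{-10}$ relative ridge: band-limited
  respiration makes lagged designs near-collinear; the ridge is far below
  estimation noise.
* Causality grid: 512 points over (0, 2] Hz. CRB falls back to one grid
  step when a peak is narrower than the grid; peaks that do not fall to
  half maximum inside the band are truncated at the band edge and flagged.
* Unstable fitted models (companion eigenvalues on or outside the unit
  circle) and windows with degenerate spectra yield flagged missing
  records, never silent numbers.
* Welch PSD: Hann taper, 60-s segments, 50% overlap; the $Q$ statistic
  includes the DC bin (baseline removal precedes it in the pipeline).
* Flat signals: entropies are defined as 0 with a flag; a constant RR
  series passes cleaning untouched (strict inequalities in the gates).
* Problem sizes used by the heavier checks, chosen to estimate each
  quantity well: VAR recovery averages 12 runs at $T=480$; the HMM
  recovery chain runs $10^4$ epochs; the end-to-end experiment simulates
  10 subjects × 8 h per group, evaluates staging by 5-fold subject-level
  cross-validation with 300-tree forests, and diagnosis by
  leave-one-subject-out.

## 8. Known limitations

The CRI depend on respiration sensor quality through a hard gate rather
than a graded weighting. The 1.5-SD cleaning rule trades a known fraction
of genuine RSA extremes for artefact robustness; on clean synthetic data
it costs about 30–50% of the log-scale coupling amplitude, uniformly
across groups. The resonance-index convention (unit capacitance,
CRQ = F_A/CRB, CRR = CRB/(2π F_A²)) is one consistent reading of the
series-RLC analogy; other normalisations of the same quantities would
rescale CRQ and CRR without changing their ordering. A-phase subtypes
with low somatomotor and autonomic impact (A1) are detected mainly
through the resonance features and are the hardest class, in simulation
as in real data. Among the macro stages, the S2/S3 boundary is the
hardest under subject-level generalisation: the feature set deliberately
excludes the mean heart rate (not one of the 21 features), so
neighbouring NREM stages must be separated by variability and coupling
features alone, and per-subject differences in coupling gain eat into
those margins. The layer-2 A/NA detector therefore operates at the
equal-recall point estimated from its training out-of-bag predictions —
balanced detection of a roughly 1:4 event — rather than at the
majority-vote argmax, which under-detects A-phases.
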