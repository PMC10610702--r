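---
title: "Entropy-based rs-EEG classification: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based rs-EEG classification: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the signal model, the entropy estimators and their exact conventions, the
cross-validation protocol, and every place where a choice had to be made
that the workflow's usual description leaves open.

## 1. Problem and pipeline

The package targets two-class classification of resting-state EEG
(Parkinson's disease versus normal control) from 14-channel, 128 Hz,
eyes-closed recordings of a few minutes, and entropy-based monitoring of
individual subjects over time. The pipeline is: Butterworth band-pass
(0.5–32 Hz, order 5, zero-phase) → segmentation into 5 non-overlapping
segments of `L_EEG` samples → ±85 µV artifact thresholding → 4-level db4
DWT, reconstructing 9 single-subband signal variants per channel → one of
seven entropy estimators per (channel, variant) → support-vector
classification under a two-stage repeated stratified K-fold protocol,
summarised as the mean validation accuracy `A_RKF`.

## 2. The synthetic cohort generator

Clinical rs-EEG data of this kind are private, so the generator is a
first-class module, not a test fixture. Each channel is a per-band sum of

* band-limited Gaussian noise — white noise filtered by a 4th-order
  Butterworth band-pass (low-pass for the delta band) and rescaled to unit
  variance — weighted by `sqrt(irregularity)`, and
* a narrowband oscillator at the band centre, weighted by
  `sqrt(1 - irregularity)`,

with band weights `sqrt(p_b)` from the profile's relative band powers, the
whole channel rescaled to `amplitude_uV` (default 15 µV standard
deviation). Defaults: the control profile concentrates power in alpha with
irregularity 0.25; the disease-like profile elevates delta/theta power
(0.40/0.25) with irregularity 0.70, making the most informative frequency
content lie below 4 Hz — the structure the pipeline is meant to recover.

Three generator choices deserve explanation:

* **Oscillator coherence.** A pure sinusoid would give every subject a
  fixed inter-band phase signature shared by all of its segments. Under
  segment-level cross-validation splits, a classifier can then memorise
  subjects: an identical-profile null cohort scored `A_RKF` ≈ 0.81 with
  infinitely coherent oscillators. Real cortical rhythms have finite
  coherence, so each oscillator carries a slow Brownian phase drift
  (increment sd `1/sqrt(fs)` per sample, roughly 1 s coherence time,
  linewidth ≈ 0.2 Hz — negligible against band widths). Segments of one
  record are then statistically exchangeable with segments of any other
  record of the same profile, and the null cohort scores `A_RKF` ≈ 0.55.
* **Amplitude.** 15 µV keeps clean signals essentially never above the
  85 µV artifact threshold (5.7 sd), as in clinical recordings where about
  five segments per subject survived thresholding; artifacts are injected
  explicitly (raised-cosine pulses, ≤ 0.25 s, Poisson times) when the
  rejection path is exercised.
* **Direction of the entropy effect.** At the configuration used
  throughout (FuzzyEn, m = 1, r = 0.15 × sd, r2 = 5) the estimator is
  dominated by the small-scale density of first differences. Signals
  dominated by slow delta content have concentrated differences, so the
  disease-like profile scores *lower* fuzzy entropy than the control
  profile in this generator, far beyond the |Cohen's d| ≥ 1 separation the
  test suite requires of the class-effect dial.
  Classification and monitoring only use that the classes differ; the
  monitoring direction flag is reported relative to labelled references,
  not with a hard-coded clinical sign.

The generator does not attempt physiological realism: no neural mass
dynamics, no volume conduction or inter-channel correlation, no ocular
waveform library. A green test therefore establishes that the pipeline
recovers planted spectral/irregularity structure — not that it would reach
any particular accuracy on clinical data.

## 3. Entropy estimator conventions

All estimators operate on lag-embedded templates
`a(i) = [x_i, x_{i+delay}, ..., x_{i+(m-1)delay}]`. Conventions that the
usual formulations leave ambiguous are fixed as follows.

* **SVDEn** uses base-2 logarithms so the normalisation by `log2 m` yields
  a true [0, 1] range; an all-zero series has no singular-value
  distribution and is a degenerate input, while a constant non-zero series
  is rank one and scores 0.
* **PermEn** breaks rank ties by stable index order and normalises by
  `log2 m!`.
* **SampEn** treats `C(m, r)` as the *proportion* of ordered template
  pairs (i ≠ j, all `N − m + 1` constructible templates) within Chebyshev
  distance `r = r_factor × sd`. Proportions rather than raw counts are
  required for the identity SampEn(constant) = 0, because the number of
  templates differs between lengths m and m + 1. Zero matches at either
  length make the statistic undefined: the estimator returns `NA` with a
  classed warning and feature assembly refuses to impute, failing loudly
  with the segment, channel and variant named.
* **CoSiEn** uses the angular distance `acos(cosine similarity)/π`
  (cosine clamped to [−1, 1]); the printed "distance" in the source
  formulation is not a metric and cannot produce a probability. Zero-norm
  templates are excluded from pairing. The entropy is the binary Shannon
  entropy of the match proportion `B`, with `B ∈ {0, 1}` scoring 0.
* **FuzzyEn** mean-centres templates, uses the Chebyshev distance, and the
  membership `exp(−d^{r2}/r)` — the natural reading of the garbled
  printed exponent, consistent with `r2` being called a membership
  exponent. Averages run over all `N − m + 1` constructible templates
  (the printed denominators `N − m`, `N − m − 1` are off by one against
  the number of templates they enumerate; we follow the templates actually
  built). For m = 1 centred length-1 templates are identically zero, so
  `φ^1 = 1` and the value reduces to `−ln φ^2`; an exact fast path
  exploits this (the centred 2-templates reduce to scalars
  `u_i = (x_i − x_{i+1})/2`), with a sorted traversal that skips pairs
  whose membership underflows `exp(−50)` — a truncation below 1e−13 on
  the pair mean, verified against the direct O(N²) implementation at
  1e−12. Standard deviations for ×sd tolerances use the population
  formula on the analysed series (per segment, per variant), so the
  tolerance adapts to each series; whether a whole-record sd was intended
  in the original workflow is unknowable and the per-segment reading keeps
  segments independent.
* **PhaseEn** maps `atan2` angles of the second-order difference plot to
  [0, 2π), accumulates per-sector *angle mass* (not counts), and
  normalises by `log K` so the log base cancels. If every angle is exactly
  zero the value is defined as 0 with a warning.
* **AttnEn** uses strict local extrema, the four interval families
  (max–max, min–min, max–next-min, min–next-max), Shannon entropy with the
  natural log for each empirical interval distribution, and their mean; an
  empty family contributes 0, and a series with no maximum or no minimum
  is degenerate.

Hyperparameter grids: SVDEn/PermEn m = 2…10 (delay 1), SampEn m = 1…3,
CoSiEn m = 2…3, FuzzyEn m = 1…2 with r2 = 1…5, PhaseEn K = 2…10, AttnEn
parameterless. Tolerance ranges written "0.05…0.5" are realised as the
lattice 0.05, 0.10, …, 0.50: it matches both printed endpoints and the
reported optimum r = 0.15 lies on it.

## 4. Preprocessing choices

* **Zero-phase filtering** (forward–backward, effective order doubled) is
  standard EEG practice and avoids phase-distorting the subband
  reconstructions; the one-pass alternative is not offered.
* **Order of operations** is fixed as filter → segment → reject, with the
  amplitude rule applied to whole segments (a segment is rejected iff any
  sample on any channel strictly exceeds the threshold; exactly 85 µV is
  kept). Rejecting whole segments preserves the per-segment feature
  contract; a `clip` mode (clamp instead of reject) preserves the
  alternative reading of amplitude thresholding.
* **Edge settle.** One second is discarded at the record start before
  segmentation: the 0.5 Hz high-pass edge of the zero-phase filter leaves
  a warm-up transient that would otherwise be counted as an artifact.
* **Wavelet boundary handling** is symmetric (half-sample) extension, a
  common default that preserves perfect reconstruction; reconstructions
  are produced by zeroing all other coefficient vectors and inverting, so
  the additivity identities (x = cA4 + ΣcD; cAk = cA(k+1) + cD(k+1)) hold
  to machine precision and are tested. Note the 0.5–32 Hz pre-filter
  attenuates the nominal cD1 band (32–64 Hz): cD1 carries filter roll-off
  residue but is still computed, because downstream analyses enumerate it.

## 5. Classification protocol

The classifier is a C-SVC trained by SMO (second-order working-set
selection, tolerance 1e−3, iteration cap 20 000 — deterministic and
near-optimal when hit; the cap matters only for large C on non-separable
data). The solver was cross-checked against a reference SVC implementation
during development; the shipped tests pin its behaviour (exact separation,
chance-level nulls, leakage canary).

Protocol choices the workflow description leaves open:

* **Hyperparameter grid**: linear kernel with C ∈ {0.1, 1, 10, 100}, and
  RBF crossed with width ∈ {1/(p · mean feature variance), 0.01, 0.1}.
  Grid order encodes the tie-break: linear before RBF, smaller C first.
* **Standardisation**: per-fold z-scoring fitted on training folds only
  (SVCs are scale-sensitive and entropy features have heterogeneous
  ranges). A canary test asserts that shifting validation-fold values
  leaves training-fold statistics bit-identical.
* **Stage seeding**: stage 1 (selection, N = 10 partitions) and stage 2
  (evaluation, N = 30 partitions) draw their stratified partitions from
  distinct seed streams, so the evaluation partitions are never seen
  during selection.
* **Split unit**: `segment` mirrors the protocol this package models
  (segments treated as independent observations). Because all 5 segments
  of a subject then straddle training and validation, any subject-specific
  signal inflates accuracy; `split_unit = "subject"` keeps subjects intact
  and is the honest setting for subject-level claims. The package defaults
  to `segment` for fidelity and documents the optimism (a dedicated test
  constructs subject-signature data and shows segment-level splits scoring
  far above subject-level ones).

## 6. Feature assembly, selection, monitoring

Features are named `channel|variant|method|params` so any reported number
is traceable to its full parameterisation. The DWT runs per segment
(segment-local), not on the whole record before cutting: segments are
declared independent observations, and per-segment transforms keep them
so. Greedy forward selection evaluates each candidate set at a reduced
budget (N = 5 partitions) — the search is O(F²) in cross-validation runs —
and re-scores the selected curve at the full protocol; ties break
lexicographically by feature name, making selection invariant to column
order. Monitoring histograms share equal-width bins across classes
(Sturges' rule on the pooled reference range) so class references and the
subject trajectory are directly overlayable; the per-visit change flag is
explicitly not a diagnosis.

## 7. Known limitations

* The simulator's stationary, uncorrelated-channel world cannot support
  claims about clinical accuracy, hemispheric effects, or which channels
  matter in real PD; those require real cohorts.
* `A_RKF` under segment-level splitting is an optimistic estimate whenever
  subject-specific structure exists; prefer subject-level splits for
  generalisation claims.
* The EDF support is deliberately minimal (16-bit, one-second records,
  equal rates, no annotations).
* SampEn features can be undefined at small tolerances on short segments;
  the pipeline surfaces this as a hard assembly error rather than imputing,
  which is the right default but means grid sweeps over tiny r may abort
  on degenerate segments.
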