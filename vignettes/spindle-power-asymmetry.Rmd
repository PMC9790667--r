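---
title: "Methods: interhemispheric spindle power asymmetry in infant EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interhemispheric spindle power asymmetry in infant EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlespa)
```

## The measurement

Sleep spindles are transient 11–15 Hz oscillatory bursts of N2 non-REM
sleep, generated by thalamocortical circuits. After a unilateral perinatal
brain injury, spindles over the lesioned hemisphere can be weaker than their
homologous counterparts, and the degree of that asymmetry carries prognostic
information about the development of unilateral cerebral palsy (UCP).

`spindlespa` quantifies this as the **spindle power asymmetry** (SPA): for a
scalp region with homologous left/right bipolar derivations, the ratio of
mean spindle power over the lesioned hemisphere to the mean spindle power
over the non-lesioned hemisphere,

$$\mathrm{SPA} = \frac{\bar P_{\text{lesioned}}}{\bar P_{\text{non-lesioned}}},$$

where $\bar P$ is the across-event mean of each event's mean sigma-band
power ($\mu V^2$). SPA is dimensionless; 1 means symmetry and values below 1
mean weaker spindles over the lesion. Five regions (fronto-central,
fronto-temporal, centro-temporal, centro-occipital, temporo-occipital)
crossed with three bands (full 11–15 Hz, slow 11–13 Hz, fast 13–15 Hz) give
15 SPA indexes per subject.

## Signal path and its assumptions

1. **Acquisition band.** Referential EEG (ten 10–20 electrodes, 256 Hz) is
   band-passed 0.3–70 Hz. All filters in the package are *zero-phase
   frequency-domain transfers* with raised-cosine band edges: unity passband
   gain, exact zero phase (burst timing is preserved), $O(n\log n)$. A
   forward–backward FIR kernel would behave identically in the passband but
   the 0.3 Hz edge would need a kernel of several thousand taps; the
   frequency-domain realization is the equivalent standard choice.
   Recordings not at 256 Hz are first resampled with an anti-aliasing
   filter.
2. **Montage.** Ten bipolar derivations: the eight-derivation longitudinal
   clinical montage plus the centro-temporal pair C3-T3/C4-T4, synthesized
   from referential channels (the clinical montage reports five regions but
   lists only eight derivations; the region-to-derivation map is
   configurable via `region_map()`).
3. **N2 restriction.** Only visually staged N2 segments are analysed
   (annotations or sidecar CSV); subjects with under 300 s of N2 are
   excluded. A per-sample map back to recording time is kept so event onsets
   are reported in original time.
4. **Detection.** Per derivation: sigma band-pass (11–15 Hz), envelope =
   magnitude of the analytic signal smoothed by a 0.2 s moving average,
   threshold = max(mean + 2 SD of that derivation's N2 envelope, 5 µV),
   supra-threshold runs merged across gaps < 0.25 s, kept if 0.5–3 s long.
   The relative threshold is computed *per derivation*, never pooled across
   hemispheres: pooling would suppress detection on the low-amplitude
   (lesioned) side and inflate SPA mechanically. Each event's oscillation
   frequency is the interpolated peak of its tapered, zero-padded spectrum
   inside 11–15 Hz (exact ties break to the lower frequency); 13.0 Hz
   classifies as fast. Event power is the mean squared sigma-filtered
   signal over the detected interval; band-specific regional power averages
   the event powers of the events classified into that band (the
   alternative — integrating band-limited PSD across pooled samples — is
   not the default).

Because the acquisition passband is flat across the sigma band and both
filters are zero-phase transfers, their composition equals the sigma filter
alone; the pipeline skips the redundant pass (a tested, mathematically exact
identity, not an approximation).

## Statistical stage

Mirroring the clinical analysis: Shapiro–Wilk is computed per group/index as
a logged justification for nonparametric testing (it never changes the
analysis path); each of the 15 indexes is compared between outcome groups
with the Mann–Whitney U test (U = min(U₁,U₂), mid-ranks for ties). Up to
n₁·n₂ ≤ 400 the two-tailed p is **exact**, from the permutation distribution
of the rank sum computed by a shift-algorithm convolution (valid under
ties); beyond that the tie-corrected normal approximation is used. The
13-vs-27 cohort (product 351) therefore gets exact p-values. No
multiple-testing correction is applied to the primary p-values — matching
the original analysis — but Holm-adjusted values are printed in a separate
column for transparency.

Indexes significant at α = 0.05 enter a forward-conditional logistic
selection: entry on the smallest score-test (Rao) p ≤ 0.05, removal on
likelihood-ratio p ≥ 0.1. We use the exact likelihood-ratio removal test
(refitting) rather than the conditional-estimates approximation some
packages use — same semantics, better statistic. With well-separated
biomarkers, complete separation is common: it is flagged, and reported
coefficients then come from a weakly ridge-penalized IRLS refit (λ = 0.01,
intercept unpenalized) so Wald statistics stay finite; selection decisions
are unaffected. Nagelkerke R² and the fraction correctly classified at
probability 0.5 summarize the model.

The best predictor's ROC uses the rank (concordant-pair) AUC oriented so
*lower* SPA predicts UCP, with the Hanley–McNeil standard error and a
truncated asymptotic 95% CI. Fixed-cutoff diagnostics classify UCP when
SPA < 0.65 (a value exactly at the cut-off counts as typical). Grubbs'
two-sided single-outlier test (α = 0.05) screens each index overall and per
group; iterative re-testing after removal is available as an option.

## The synthetic cohort: what it emulates

Clinical recordings cannot ship with the package, so every stage is
validated against a seeded generator of synthetic infant N2 EEG.

**Background** is independent 1/f^1.5 Gaussian noise per electrode, 10 µV
RMS — the sigma-band content (~2–3 µV per derivation) matches the envelope
noise floor against which infant spindles (tens of µV) are detected.
**Spindles** are Tukey-tapered sinusoids, 1–2 s, 30 µV, frequencies from an
equal mixture of a 12 Hz (slow) and a 14 Hz (fast) component truncated
0.2 Hz away from the 13 Hz boundary (so homologous events classify into the
same band on both hemispheres), injected simultaneously on homologous
left/right electrode groups at 2 events/min/region with hard-core spacing so
events never overlap or merge. The lesioned hemisphere's copy is scaled by a
per-region amplitude factor $a$; since power scales as amplitude², the
implied SPA is $a^2$.

**Leakage routing.** The five regional derivations per hemisphere are
differences of only four electrode potentials, so every injection obeys
FT = FC + CT and CO = CT + TO sample-wise — *no* referential source pattern
can confine a burst to a single derivation, and naive injection smears a
targeted asymmetry across regions. Each event is therefore injected as a
potential pattern whose leakage is routed away from one **protected
region** (default CO, the headline biomarker): other regions' patterns put
zero amplitude on the protected derivation, and the protected region's own
unavoidable leakage is split at half amplitude, which the detector's
threshold rejects at default settings. Consequently the protected region's
measured SPA equals $a^2$ cleanly, while other regions' measured SPA is a
detected-event blend of their own factor with the factors of regions whose
full-amplitude leakage lands on them (`ground_truth_spa()` returns exactly
this blend). This is a deliberate refinement of "inject on referential
sources": the montage's rank deficiency makes five independently
controllable regional asymmetries physically impossible.

**Cohort calibration.** 13 UCP / 27 typical subjects, ~55% left lesions.
Per-region factors are log-normal; UCP medians are the square roots of the
study's reported regional medians (CO calibrated to the centro-occipital
*fast* median 0.56; the frontal slow "typical 1.97" entry is treated as a
typo and not used). Dispersions are `sdlog` 0.02 (UCP) and 0.12 (typical):
the typical group then reproduces the reported typical IQR (~0.3), while
the UCP spread is set to reproduce the reported *individual-level*
separability (AUC ≈ 0.93, sensitivity 100% / specificity 92.3% at the 0.65
cut-off) — the reported UCP IQR of 0.35 at median 0.56 is jointly
inconsistent with that diagnostic quadruple (it would put roughly a third of
UCP subjects above the cut-off), so the two could not both be matched; we
chose the diagnostics, which the acceptance checks exercise. These
constants were fixed once from the overlap arithmetic, not tuned against
test outcomes.

**What passing does and does not show.** The generator has stationary
backgrounds, stereotyped bursts, symmetric noise and perfectly labelled N2;
real infant EEG has artefacts, non-stationary amplitude, age-varying
spindle morphology and imperfect staging. Green tests demonstrate that the
*pipeline* recovers known asymmetries, that the detector behaves at a
realistic SNR, and that the statistics equal their exact oracles — not that
the clinical effect sizes would replicate on new infants.

## Numerical choices and degenerate inputs

* Seconds from recording start everywhere; intervals half-open [start, end).
* Supra-threshold runs never span N2 segment boundaries.
* Event spectra: Hann taper, zero-padded FFT (≥ 2048 points, 0.125 Hz bins
  at 256 Hz) with parabolic sub-bin interpolation clamped to the band.
* Exact Mann–Whitney: mid-ranks doubled to integers; the two-sided p is
  the probability mass of rank sums at least as far from n₁n₂/2 as
  observed.
* Constant samples: Shapiro–Wilk and Grubbs refuse (degenerate variance);
  empty derivations are skipped with a warning; a missing SPA (no events or
  excluded channel) carries a reason code and propagates as missing into the
  statistics (pairwise deletion per index).
* Determinism: all generator randomness derives from integer seeds; the
  analysis stage contains no randomness, so identical configuration and
  seed reproduce byte-identical tables and reports.

## Problem sizes used in the test-suite

Unit tests use 340 s subjects (320 s of N2); end-to-end checks use the
default 600 s subjects — 10 subjects per asymmetry level for recovery, 20
for detector fidelity, and 25 replicate 40-subject cohorts for the
outcome-separation property; the null-calibration check simulates 500
SPA-level index columns. These sizes give Monte-Carlo error comfortably
below the asserted tolerances.

## Known limitations

* EDF support covers the clinical subset used here (one rate per ordinary
  signal, µV units, TAL annotations); it is not a general EDF library.
* The stepwise "conditional" removal test is the exact likelihood-ratio
  version, which can differ from the conditional approximation in marginal
  cases.
* Non-protected regions' synthetic SPA is a leakage blend, not a free
  parameter — a montage property, not an implementation bug.
* Detection parameters are defaults of the detector family, exposed in
  `detector_params()` and recorded in run metadata, not values validated on
  clinical recordings.
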