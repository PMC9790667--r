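# spindlespa

Automated analysis of **interhemispheric sleep spindle power asymmetry
(SPA)** in infant N2-sleep EEG after unilateral perinatal brain injury, and
evaluation of SPA as an early biomarker of unilateral cerebral palsy (UCP).

Infants with a one-sided perinatal stroke may develop weaker sleep spindles
over the lesioned hemisphere. For each scalp region with homologous
left/right bipolar derivations the package computes

    SPA = P̄_lesioned / P̄_non-lesioned

where `P̄` is the across-event mean of per-event mean sigma-band power
(µV²). Five regions (fronto-central, fronto-temporal, centro-temporal,
centro-occipital, temporo-occipital) × three bands (full 11–15 Hz, slow
11–13 Hz, fast 13–15 Hz) give 15 SPA indexes per subject; SPA < 1 means
weaker spindles over the lesion.

The package covers the full path from raw EDF to the clinical report:

* **EDF/EDF+ I/O** — referential recordings, TAL annotations, sidecar CSVs
  for N2 staging and bad channels (`read_edf()`, `write_edf()`).
* **Preprocessing** — zero-phase 0.3–70 Hz band-pass, resampling to 256 Hz,
  standard bipolar montage, N2 extraction with eligibility checks
  (`apply_filters()`, `make_bipolar()`, `extract_n2()`).
* **Spindle detection** — per-derivation sigma-envelope thresholding
  (mean + 2 SD, 5 µV floor, 0.5–3 s, 0.25 s merge gap), per-event
  oscillation frequency and mean power (`detect_spindles()`).
* **SPA metrics** — regional band powers and the 15 indexes
  (`spa_indexes()`, `spa_table()`).
* **Statistics** — exact/tie-corrected Mann–Whitney U, forward-conditional
  logistic selection (score-test entry, likelihood-ratio removal),
  rank AUC with Hanley–McNeil SE, fixed-cutoff diagnostics at SPA < 0.65,
  Grubbs outlier screening (`analyze_cohort()` and the individual
  functions).
* **Synthetic cohorts** — seeded infant-EEG generator with known
  ground-truth events and asymmetry factors, calibrated to the study's
  group structure (13 UCP / 27 typical) (`synth_cohort()`,
  `synth_subject()`).

A thin command-line front end with `simulate`, `detect`, `spa`, `stats` and
`run-all` subcommands is installed at `inst/cli/spindlespa.R`.

## Worked example

Simulate a cohort with the default design and run the pipeline end-to-end:

```r
library(spindlespa)

cohort <- synth_cohort(cohort_spec(seed = 7))      # 13 UCP vs 27 typical
res <- run_pipeline(run_config(), cohort = cohort)
res$report
#> Diagnostic report: 13 UCP vs 27 typical
#>   15 of 15 SPA indexes significant at alpha = 0.05
#>   best predictor: CO_slow_SPA (AUC 1.000)
#>   at SPA < 0.65: sens 100.0%, spec 96.3%, PPV 92.9%, NPV 100.0%

cmp <- res$report$comparisons
cmp[cmp$index == "CO_fast_SPA", c("median_ucp", "median_typical", "U", "p")]
#>    median_ucp median_typical U            p
#> 12  0.5670713       1.031259 0 1.662065e-10
```

The UCP group's centro-occipital fast SPA sits near 0.57 (spindle power
over the lesioned hemisphere roughly half of the healthy side) while the
typical-outcome group is symmetric near 1.0; the Mann–Whitney U of 0 and
the exact p-value reflect complete group separation in this draw, and the
0.65 cut-off separates the outcomes almost perfectly. One synthetic subject
with a known factor behaves the same way:

```r
sp  <- subject_spec(asymmetry = c(CO = 0.8), lesion_side = "left", seed = 42)
sub <- synth_subject(sp)
out <- process_subject(sub$recording, "left", run_config(),
                       segments = sub$segments)
round(out$indexes$spa["CO_full_SPA"], 2)   # ~0.64 = 0.8^2
#> CO_full_SPA
#>        0.67
```

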