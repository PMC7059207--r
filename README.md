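# cadmrmc

Observer-performance analysis for screening with automated 3D breast
ultrasound (ABUS) when a computer-aided detection (CAD) system is used as an
**independent validator** of radiologists' findings — rather than as a
conventional prompting aid.

In the CAD-validation reading paradigm, a radiologist reads the ABUS exam
unaided and marks suspicious lesions with a BI-RADS category and a
level-of-suspiciousness (LOS) score on a 0–100 scale (anchors 21/41/61/81
for BI-RADS 2–5). A finding counts as positive only if a CAD region lies
within **10 mm spherical distance** of the reader's marker in the same ABUS
volume; all other findings are rejected. Because most reader false positives
stem from benign lesions and acoustic artefacts that a well-tuned CAD
system does not mark, validation trades a small sensitivity loss for a
specificity gain concentrated in the screening-relevant operating range.

`cadmrmc` is aimed at observer-study methodologists and CAD researchers. It
implements the complete analysis chain:

* **Matching & rejection** — inclusive ≤10 mm criterion, per-volume frames,
  nearest-qualifying-mark tie-breaks; rejected findings are classified
  against truth (missed cancer / benign / normal tissue or artefact) and by
  mechanism (`no_cad_in_case`, `cad_total_miss`, `distance_exceeded`,
  `wrong_volume`), with Table-style per-reader summaries and a
  double-reading workload calculator.
* **AFROC** — case-level scores by the highest-rated-lesion rule
  (false-positive findings in malignant cases are omitted; unmarked cases
  carry a sentinel below every score), the empirical AFROC curve, and the
  figure of merit θ = P(X_diseased > X_nondiseased) + ½P(tie), identical to
  the trapezoidal area under the curve.
* **PROPROC** — maximum-likelihood proper binormal ROC fits
  (Metz–Pan (c, d_a) parameterization via likelihood-ratio thresholding, so
  fitted curves never hook), full AUC in closed form, partial AUC on
  FPF ∈ [0, 0.2], and sensitivity at 90% specificity.
* **MRMC inference** — Dorfman–Berbaum–Metz jackknife pseudovalue ANOVA
  (readers and cases random) with the Hillis denominator and degrees of
  freedom, per-reader paired jackknife t tests, and Wald-type intervals.
* **Synthetic studies** — a Roe–Metz-style generator reproducing the study
  design (120 exams: 30 malignant / 30 benign / 60 normal over ~375
  volumes; 8 readers; CAD at ~82% lesion sensitivity and 1 false positive
  per volume) so the whole pipeline is testable without image data.

Everything is tidyverse-native: tibbles in, tibbles out, `tidy()`/`glance()`
methods, and `autoplot()` for curves, fits and reports.

## Worked example

The package bundles the per-reader rejection count table of an
eight-reader, 120-case ABUS reading study and a fixture builder that
realizes those counts geometrically, so the summary statistics can be
recomputed through the actual matching pipeline:

```r
library(cadmrmc)

study <- study_from_rejection_counts(example_rejection_counts())
rs <- summarize_rejections(validate_findings(study))
attr(rs, "summary")[1, c("statistic", "pct_rejected", "pct_normal",
                         "pct_birads3", "pct_birads4", "pct_birads5")]
#> # A tibble: 1 × 6
#>   statistic pct_rejected pct_normal pct_birads3 pct_birads4 pct_birads5
#>   <chr>            <dbl>      <dbl>       <dbl>       <dbl>       <dbl>
#> 1 mean              42.6       35.7        47.5        42.1        10.4
```

So on average 42.6% of BI-RADS ≥3 findings are discarded by CAD
validation; 35.7% of the rejections are normal tissue or artefacts, and
rejections are dominated by BI-RADS 3 (47.5%) over BI-RADS 4 (42.1%) and
BI-RADS 5 (10.4%).

A full synthetic study runs end to end in one call:

```r
study <- simulate_study(sim_config(), seed = 1)
report <- analyze_study(study)
report
#> ABUS CAD-validation study report
#>   readers: 8 | positive findings rejected (mean %): 55.2
#>   auc           cad_validated 0.830 vs unaided 0.813 | P = 0.499
#>   pauc          cad_validated 0.131 vs unaided 0.102 | P = 0.021
#>   sens_at_spec  cad_validated 0.717 vs unaided 0.449 | P = 0.087
```

The partial AUC over the high-specificity interval improves significantly
while the full AUC barely moves — validation removes low-threat false
positives and (occasionally) a CAD-missed cancer, reshaping the curve only
where specificity is high. `tidy(report)` returns the Table-1-style layout,
`autoplot(report, "pauc")` plots per-reader estimates with intervals, and
`run_pipeline(out_dir, simulate = list(config = sim_config(), seed = 1))`
writes the CSV/JSON report bundle.

## Package layout

| Area | Functions |
| --- | --- |
| Study data | `new_study()`, `load_study()`, `write_study()`, `load_study_json()`, `spherical_distance()`, `anchor_scale()` |
| CAD validation | `match_criterion()`, `match_finding()`, `validate_findings()`, `classify_rejection()`, `diagnose_cause()`, `summarize_rejections()`, `double_read_workload()` |
| AFROC | `build_case_scores()`, `afroc_fom()`, `afroc_curve()`, `trapezoid_area()` |
| PROPROC | `bin_scores()`, `fit_proproc()`, `proproc_curve()`, `full_auc()`, `pauc()`, `sens_at_spec()` |
| MRMC | `jackknife_pseudovalues()`, `dbm_anova()`, `analyze_study()` |
| Simulation | `sim_config()`, `generate_truth()`, `generate_cad_marks()`, `generate_reader_sessions()`, `simulate_study()` |
| Pipeline | `run_pipeline()`, `load_pipeline_config()`, `study_from_rejection_counts()` |

See the methods vignette (`vignettes/cad-validation-methods.Rmd`) for the
statistical background, modelling assumptions, and design choices.
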