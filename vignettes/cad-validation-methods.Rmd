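---
title: "CAD validation of reader findings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAD validation of reader findings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cadmrmc)
```

## The reading paradigm

Supplemental screening of dense breasts with automated 3D breast
ultrasound (ABUS) improves cancer detection but inflates recalls: many
reader findings are benign lesions or acoustic-shadowing artefacts. In the
CAD-validation paradigm analysed by this package, the radiologist reads
unaided, marking each suspicious lesion with a 3D position, a BI-RADS
category and a level-of-suspiciousness (LOS) score on 0–100 (anchored at
21/41/61/81 for BI-RADS 2–5). A CAD system then acts as an independent
second opinion at the *finding* level: a reader finding is kept only if a
CAD region lies within a spherical match distance of the marker in the same
ABUS volume; everything else is discarded. Since a well-tuned CAD
discriminates cancers from benign lesions and artefacts, the discarded set
is dominated by non-malignant findings, and performance in the
high-specificity range improves at a small cost in sensitivity.

`cadmrmc` implements the full analysis of such a study: finding validation
and rejection taxonomy, AFROC figures of merit, proper binormal curve
fitting, and multi-reader multi-case (MRMC) significance testing, plus a
synthetic study generator used throughout the test suite.

## Matching and the rejection taxonomy

**Criterion.** A match is an inclusive spherical distance
`d ≤ max_distance` (default 10 mm) between marker and CAD region, within
the same volume (`match_criterion()`). Coordinates live in millimetres in
per-volume frames with the origin at a corner of the bounding box; matching
is never attempted across volumes because ABUS views are acquired
independently and share no registration. Ties between equidistant
qualifying marks break deterministically (lowest volume id, then lowest
mark row).

**Localization radius.** Deciding whether a marker "points at" a lesion
uses `max(diameter/2, max_distance)` around the lesion center. Reference
truth in such studies is a drawn outline; with only centers and diameters
representable, the radius floor reproduces the important behaviour that a
marker inside a large tumor can be more than the match distance from a CAD
mark on the same tumor.

**Taxonomy.** Each rejected finding receives a truth class — a missed
cancer (`malignant_FN`) if it localizes a malignant lesion, `benign_TN` if
a benign one, else `normal_tissue_artefact_TN` — and a mechanism:

* `no_cad_in_case` — the case carries no CAD marks at all;
* `distance_exceeded` — CAD marked the lesion in the reader's volume but
  beyond the match distance (large tumors);
* `wrong_volume` — a multi-volume lesion marked by CAD only in a volume
  other than the reader's;
* `cad_total_miss` — no CAD mark near the lesion in any volume.

The precedence is `no_cad_in_case`, then same-volume `distance_exceeded`,
then `wrong_volume`, then `cad_total_miss`. For findings that localize no
lesion, a same-volume mark beyond the criterion reports
`distance_exceeded`, otherwise `cad_total_miss`. A literal reading of the
alternative — any same-volume mark, however distant, implying
`distance_exceeded` — would let an unrelated false-positive mark 40 mm away
mask a genuine total miss, so the lesion-centred reading is used.

**Summaries.** `summarize_rejections()` reports, per reader, rejected
counts and percentages among positive (BI-RADS ≥ 3 by default) findings,
and the composition of rejections by truth class and BI-RADS category.
Across-reader means are unweighted arithmetic means of the per-reader
percentages; printed values use round-half-away-from-zero to one decimal,
the convention of clinical tables. Readers with a zero denominator are
excluded from the corresponding mean and reported in an attribute.

## AFROC analysis

Case scores follow the highest-rated-lesion rule (`build_case_scores()`):
a malignant case is scored by the highest LOS among findings that localize
a malignant lesion; false-positive findings in malignant cases are omitted
entirely, so neither the reader nor CAD is rewarded while the cancer
itself is missed or rejected. A non-malignant case is scored by its
highest-rated finding of any kind. Unmarked cases carry a sentinel that
ranks strictly below every real score; sentinel–sentinel comparisons count
one half. The nondiseased pool defaults to benign and normal cases
together (the pool over which specificity is defined); a `normal_only`
switch supports sensitivity analyses.

The figure of merit is the two-sample rank statistic
θ = mean over (diseased, nondiseased) pairs of 1·[d > n] + ½·[d = n],
computed via midranks in `afroc_fom()`; `afroc_curve()` sweeps thresholds
over the observed scores and its trapezoidal area equals θ identically
(this identity is exercised to 1e-12 over a thousand random score sets in
the test suite). θ is invariant under strictly increasing transforms of
the scores, which is what makes latent-scale simulation legitimate.

## The proper binormal (PROPROC) model

The conventional binormal model (nondiseased latent N(0,1), diseased
N(a/b, 1/b²)) yields improper ROC curves with "hooks" whenever b ≠ 1. The
proper binormal model instead thresholds the *likelihood ratio* of the
same latent pair. Since log LR is quadratic in the latent score, each
threshold maps to an interval (b > 1) or a pair of tails (b < 1), and the
curve — parameterized by c = (b−1)/(b+1) ∈ (−1,1) and
d_a = a√2/√(1+b²) ≥ 0 — is proper by construction: slope non-increasing,
never below chance. At c = 0 it reduces to the equal-variance binormal
curve with AUC = Φ(d_a/√2); in general
AUC = Φ(d_a/√2) + 2F(−d_a/√2, 0; −(1−c²)/(1+c²)) with F the standard
bivariate normal CDF (`full_auc()`, cross-checked against numerical curve
integration at 1e-8 in the tests).

**Fitting.** Continuous LOS case scores are binned at the BI-RADS anchors
{21, 41, 61, 81} with half-open, left-closed intervals; the bottom bin
absorbs the sentinel (`bin_scores()`). `fit_proproc()` maximizes the
multinomial likelihood over (c, d_a) and the category cutpoints. The
cutpoints are parameterized on the probit-FPF scale through ordered
softplus increments, which keeps them automatically inside the curve's
valid threshold range for every (c, d_a); c uses atanh and d_a a log
transform. Five deterministic starts guard against the multimodality of
proper-binormal likelihoods in small samples; the convergence flag demands
a central-difference gradient norm below 1e-4·(1 + |negative log
likelihood|), a relative criterion chosen because absolute thresholds are
meaningless against finite-difference noise on likelihoods of hundreds of
cases. Perfect separation is reported honestly: d_a pinned at its upper
bound (6) with `converged = FALSE` and reason `"degenerate"` rather than a
spuriously precise estimate.

**Derived quantities.** `pauc()` integrates the fitted TPF over
FPF ∈ [0, 0.2] by adaptive quadrature (the chance-line case is returned in
closed form, exactly 0.02); `sens_at_spec()` evaluates TPF at
FPF = 1 − specificity (default 0.90). Both also exist in empirical form on
the trapezoidal curve (`type = "empirical"` / interpolation), which is
what the MRMC machinery jackknifes (below).

## MRMC inference

`dbm_anova()` implements the Dorfman–Berbaum–Metz approach: each figure of
merit is expanded into case jackknife pseudovalues
`n·θ − (n−1)·θ₍₋k₎` and the pseudovalues are analysed by a three-way
mixed ANOVA (modality fixed; readers and cases random; one observation per
cell). The modality F statistic uses the Hillis denominator
`MS(TR) + max(MS(TC) − MS(TRC), 0)` with the Hillis denominator degrees of
freedom — the modern correction for the classic DBM software lineage; a
`classic = TRUE` switch restores the uncorrected denominator. With a
single reader the procedure collapses, exactly, to a paired jackknife t
test. Under a null with the full Roe–Metz random-effect structure
(8 readers, 120 cases, 2000 replicates) the empirical type-I error of the
modality test sits inside [0.03, 0.07] at α = 0.05 in the acceptance
suite.

Confidence intervals are Wald-type on the figure-of-merit scale, truncated
to [0, 1]: single-modality intervals use the analogous
`MS(R) + max(MS(C) − MS(RC), 0)` variance with Satterthwaite-style degrees
of freedom, per-reader intervals use the per-reader jackknife standard
error with n−1 degrees of freedom. The exact interval construction behind
published tables of this kind is rarely stated; Wald-type is assumed and
recorded here. Negative variance-component estimates are truncated at zero
and surfaced via a message.

**Which numbers are fitted and which are empirical.** `analyze_study()`
reports PROPROC-fitted AUC, pAUC and sensitivity as point estimates
(falling back to NA when a reader's data are degenerate), but performs
jackknifing and the DBM test on the empirical counterparts (AFROC area,
trapezoidal partial area, interpolated sensitivity). Leave-one-case-out
maximum-likelihood refits — thousands per study — are numerically fragile
exactly where they matter (leave-one-out bins go degenerate) and the
empirical statistics are well-defined for every subset; the empirical and
fitted quantities track each other closely at these sample sizes. The
pooled estimate is the reader mean, so pooled values equal the mean of the
per-reader rows by construction.

## The synthetic study generator

`sim_config()` encodes the study design as defaults: 120 unilateral exams
(30 malignant, 30 benign, 60 normal), 2–5 volumes per case with sampling
probabilities giving a mean of 3.125 (≈375 volumes), eight readers,
malignant diameters lognormal with median 14 mm (benign 12.4 mm, both
truncated to fit the 170×150×50 mm volume), CAD at 82% marginal lesion
sensitivity and one false-positive region per volume. Ratings follow a
Roe–Metz-style latent model: class mean + lesion conspicuity (shared
across readers) + reader effect + residual, pushed through the probit link
onto 0–100 and categorized by the anchor intervals, so downstream MRMC
variance components are non-trivial by construction.

Two modelling choices deserve emphasis:

* **Reader–CAD coupling.** CAD detection is probit-linked to the same
  lesion conspicuity the readers see, with the intercept chosen so the
  *marginal* sensitivity stays exactly at its configured value. Without
  this coupling, CAD would reject a random subset of reader-detected
  cancers — including the confidently rated ones — and validation would
  *reduce* the partial AUC, contradicting the mechanism the paradigm rests
  on (cancers missed by CAD tend to be the subtle ones readers also rate
  lower). The weight defaults to 2.2.
* **Failure modes.** Marked large lesions (diameter > 2.2× the match
  distance) may receive their mark offset beyond the criterion but inside
  the lesion; multi-volume lesions may be marked in only one volume. These
  reproduce the distance-exceeded and wrong-volume rejection mechanisms
  end to end, which the acceptance suite verifies label-by-label.

Random streams are split hierarchically (truth / CAD / per-reader) with
integer-derived seeds, so one seed yields a bit-identical study and
changing the number of readers never perturbs the truth tables.

Default reader parameters (detection 0.75–0.92 for cancers, 0.60–0.80 for
benign lesions, false marks 0.04–0.18 per volume, class means 1.0 / 0.25 /
−0.2 on the probit scale) were calibrated once so that unaided empirical
figures of merit span roughly 0.73–0.88 with a positive pooled pAUC uplift
after validation — i.e. the operating regime of an eight-reader ABUS
study — and are labelled calibration, not inference. What the generator
does *not* emulate: reader-specific recall strategies, the benign-heavy
composition of real-world rejections (the synthetic rejection pool is
dominated by normal-tissue false marks instead), mammographic correlation,
and anything at the image level. Passing tests therefore demonstrate the
correctness and calibration of the *analysis machinery* under the assumed
rating model, not the clinical effect size itself, which is why the
bundled worked example (printed per-reader counts realized geometrically
by `study_from_rejection_counts()`) exists as a separate, exact
reproduction path.

## Numerical choices and degenerate inputs

* Percentages print to one decimal with round-half-away-from-zero.
* The match boundary is inclusive; distances are exact Euclidean norms.
* PROPROC curve evaluation inverts FPF(v) by bracketed root-finding at
  tolerance 1e-12; quadratures use rel.tol 1e-10 (pAUC) and 1e-12
  (bivariate normal CDF).
* Empty CAD mark sets are valid input (everything rejected,
  `no_cad_in_case`); empty truth classes raise structured errors; a reader
  with no positive findings is excluded from across-reader means with a
  note rather than propagating NaN.
* Identical modalities yield a zero F statistic and P = 1 (not 0/0); a
  zero jackknife SE in a per-reader test reports P = 1.
* The test suite and acceptance script scale replicate counts to desk
  sizes (e.g. 2000 null studies for type-I calibration, 200 replicates for
  the stochastic-dominance check, 4000-lesion cohorts for operating-point
  recovery), chosen as the smallest sizes at which the checked tolerances
  are comfortably more than three standard errors wide.

## Known limitations

* Lesion truth is center + diameter, not an outline; the localization
  radius floor is a documented approximation.
* The Obuchowski–Rochette covariance formulation of MRMC is not
  implemented; the DBM pseudovalue route with Hillis correction is.
* Fitted-curve inference (jackknifed PROPROC refits) is intentionally
  avoided; see above.
* The generator's inter-reader correlation level is a calibration default;
  no empirical correlation estimates exist to fit it to.
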