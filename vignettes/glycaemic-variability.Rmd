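---
title: "Glycaemic variability from CGM and single-draw predictive indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycaemic variability from CGM and single-draw predictive indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyvar)
```

## The problem

Continuous glucose monitoring (CGM) quantifies glycaemic variability —
the swings around mean glucose that HbA1c cannot see and that carry their
own risk of hypoglycaemia and vascular damage — but CGM is not available
at every clinic visit. Two indices computable from a *single fasting
blood draw* have been proposed as predictors of variability:

* the **GA/A1c ratio**, glycated albumin (%) over HbA1c (NGSP %).
  Albumin glycates roughly ten times faster than haemoglobin, so GA
  responds to short-lived glucose spikes that leave A1c unchanged; a high
  ratio marks recent and fluctuating hyperglycaemia.
* the **FCPR index**, fasting C-peptide (nmol/l) over fasting plasma
  glucose (mmol/l) times 100 — a basal beta-cell function index. Poor
  basal insulin secretion removes the buffer that damps glucose swings,
  so a *low* index predicts *high* variability.

`glyvar` implements the complete analysis chain linking these indices to
CGM-measured variability: the variability-metric suite, the index and
HbA1c-standard calculations, the serial-cutoff ROC procedure that turns
an index into an operating rule, the cohort statistics, and a calibrated
synthetic cohort generator so the whole pipeline is testable without
patient data (the motivating clinical dataset was never deposited).

## The analysis window

CGM recordings run ~72 h but the first hours mix sensor equilibration
with an arbitrary start time. `select_analysis_window()` keeps the 48 h
starting from the first midnight *strictly after* the device start — a
recording started exactly at 00:00 uses the following midnight. At the
5-min sampling interval of the target devices this yields exactly
576 values, and every metric below is computed on that window.

## The variability metric suite

For a windowed trace with non-missing values $x_1,\dots,x_n$:

* **SD** — sample standard deviation (`sd_ddof = 1`; the convention is
  configurable because legacy spreadsheet implementations differ, and it
  is recorded in every report). SD is the reference measure the indices
  are screened against.
* **%CV** — $100\,\mathrm{SD}/\bar x$; unit-free.
* **Range**, **IQR** — max − min and Q75 − Q25. Percentiles use linear
  interpolation between closest ranks (R type 7); IQR is the one metric
  whose value depends on the percentile convention, so it is pinned
  explicitly.
* **J-index** — $0.001(\bar x + \mathrm{SD})^2$ on mg/dl. The historical
  formula and its magnitude are mg/dl-based, so the package converts
  internally whatever the trace unit (configurable).
* **M-value** ($M_R$) — mean of $|10\log_{10}(x_i/R)|^3$ with ideal
  glucose $R$ = 5.6 mmol/l (100 mg/dl). The plain form is used; the
  amplitude-correction term (range/20) that some older formulations add is
  behind the `m_value_correction` flag, off by default.
* **IGC** — hyperglycaemic index $\sum_{x_i>U}(x_i-U)^{1.1}/(30n)$ plus
  hypoglycaemic index $\sum_{x_i<L}(L-x_i)^{2}/(30n)$ with
  $U$ = 7.8 and $L$ = 4.4 mmol/l. The thresholds are the clinical
  defaults; the exponents/scales are the standard Rodbard constants
  (only the thresholds are universal in the literature, so all four
  constants live in `metric_config()` and are echoed in reports).
  Comparisons are strict: a sample exactly at a threshold contributes 0.
* **MODD** — mean |difference| between samples exactly 24 h apart;
  needs a full 48-h window; pairs with a missing member are dropped.
* **CONGA$_n$** — SD of differences exactly $n$ h apart;
  `conga_1_24()` averages $n = 1..24$ (exactly 24 terms).

### The MAGE algorithm

MAGE (mean amplitude of glycaemic excursions) averages the amplitudes of
excursions exceeding 1 × window SD, counted peak-to-nadir or
nadir-to-peak in the direction set by the first qualifying excursion
(the classic Service convention). "Turning point" is underdetermined in
the literature, so the package fixes it precisely:

1. collapse plateaus (runs of equal values);
2. take interior turning points (sign changes of the first difference);
   when fewer than two exist the first/last samples serve as excursion
   termini, so a single sustained step still counts as one excursion —
   but when interior turning points exist the partial excursions at the
   window edges are *not* counted (they would bias the mean downward:
   a pure sinusoid must give MAGE = 2 × amplitude);
3. prune sub-threshold oscillations: repeatedly find the (leftmost)
   adjacent extremum pair with the smallest amplitude; while that
   amplitude is below 1 SD, delete the pair, first absorbing each
   deleted extremum into its surviving same-type neighbour (keeping the
   more extreme value). This merges noise wiggles into the major swings
   they interrupt;
4. qualifying amplitudes are those strictly greater than 1 SD.

A trace with no qualifying excursion returns a flagged `NA` — a valid
result, not an error. Optional pre-smoothing (`mage_smoothing`) exists
but defaults to off: 5-min CGM output is already device-averaged.

### Missing data

Metrics use non-missing values only; MODD/CONGA pairs need both members;
nothing is ever imputed. A profile requires completeness ≥ 0.9
(`min_completeness`), and each profile row records its completeness.

## Laboratory indices

`floor_fcpr()` applies the assay detection limit: below-limit values are
stored as 0.001 nmol/l with a provenance flag. `convert_hba1c()` moves
between JDS %, NGSP % and IFCC mmol/mol using the standard harmonisation
(NGSP% = JDS% + 0.4; IFCC = 10.93 × NGSP% − 23.50); the GA/A1c ratio is
defined on NGSP % (the only standard for which the published ratio
magnitudes, ≈ 2.9, are reproduced). `classify_risk()` applies the joint
rule — ratio ≥ 2.8 **and** index < 3.0 predicts high variability, both
reversed predicts low, anything else is indeterminate — with the
boundary conventions exactly as printed (≥ on the ratio, < on the
index).

## The serial-cutoff ROC sweep

The published cutoffs were found by repeating ROC analysis over serial
cutoff values until the AUC was maximal. `cutoff_sweep()` interprets
this as: sweep the glycaemic-SD dichotomisation threshold over a 0.1
mmol/l grid across the observed SD range, compute the index's AUC
against each dichotomy, keep the threshold with the highest AUC (ties
toward the lower threshold), then choose the index's operating cutoff at
that threshold by Youden's J. Grid thresholds leaving fewer than 10% of
subjects (`min_class_frac`) on either side are excluded — AUCs against a
class of one or two subjects are unstable and the published optima sit
mid-range. Because the threshold is optimised on the data the maximised
AUC is optimistic; `n_permutations > 0` quantifies that against a
permutation null and flags it in the result, and the package never
reports the maximised AUC without the construction being visible.

The combined two-criterion ROC is not uniquely defined by a pair of
binary rules; `combined_criterion_analysis()` uses the number of
satisfied high-risk criteria as the score, evaluated on the two definite
groups (indeterminate subjects excluded, as the published group counts
of 42 + 30 out of 100 imply), against the SD dichotomy. The construction
is recorded in the result rather than asserted equivalent to the
original.

## Cohort statistics

`dagostino_pearson()` implements the omnibus K2 normality test
(D'Agostino skewness z + Anscombe–Glynn kurtosis z, χ² with 2 df) —
no installed R package provides it, and it is validated against an
independent implementation in the test suite. `univariate_screen()` uses
Pearson correlation with 0/1 coding for binary factors (point-biserial);
`stepwise_regression()` is forward selection with backward elimination
on partial F-tests (entry p 0.05, removal p 0.10 — standard defaults,
configurable); `group_compare()` uses χ² (no continuity correction) for
categorical and unpaired equal-variance t-tests for continuous
variables, with a Fisher fallback for degenerate tables;
`band_distribution()` stratifies recording time into glucose bands
(default edges 2.2, 4.4, 5.6, 7.8, 10.0, 15.6, 18.8 mmol/l, left-closed
intervals) and `compare_band_distributions()` t-tests each band between
groups. **No multiple-testing correction is applied anywhere** — the
analysis chain this package reproduces applied none — and every p-value
is reported raw with that note in the JSON report.

## The synthetic cohort generator

No patient data accompany the motivating analysis, so
`generate_cohort()` produces cohorts with the statistical structure the
pipeline assumes. Per subject:

* a latent variability level $v$ (log-normal; mean 3.6 mmol/l in type 1,
  2.5 in type 2, matching the published SD-by-type means) and a chronic
  mean glucose $\mu$ (log-normal, 9.5 ± 2.9 mmol/l);
* a 72-h trace $g(t) = \mu + v\,z(t) + \varepsilon(t)$, where $z$ is a
  zero-mean unit-variance shape process (mean-reverting
  Ornstein–Uhlenbeck baseline, 2-h time constant, plus post-meal bumps
  at 07:30/12:30/19:00 with log-normal amplitudes and a ~50-min-to-peak
  kernel) and $\varepsilon$ is sensor noise (SD 0.25 mmol/l). Scaling a
  normalised shape by $v$ makes the realised glycaemic SD track $v$
  directly (r > 0.95 in cohorts of 200). Values are clipped to the
  device range 2.2–22.2 mmol/l;
* labs: HbA1c linear in $\mu$ (calibrated to 8.9 ± 1.8 NGSP% at the
  target $\mu$ distribution); GA linear in $\mu$ *and* $v$
  (`coupling_ga`, default +1.6 %GA per mmol/l of $v$), so the GA/A1c
  ratio rises with variability; FCPR log-linear decreasing in $v$
  (`coupling_fcpr`, default −0.5) from type-specific bases (0.02/0.42
  nmol/l), floored at the 0.001 nmol/l detection limit; FPG is the mean
  of the trace's 06:00–08:00 segment plus assay noise.

The coupling coefficients were calibrated once, at design time, so that
a default 100-subject cohort reproduces the published correlation
magnitudes (r(SD, GA/A1c) ≈ +0.5, r(SD, FCPR index) ≈ −0.5) and Table-1
style marginals (SD ≈ 2.9 ± 1.0, GA/A1c ≈ 2.9 ± 0.5); they are free
parameters of the generator, not estimates. What the generator does
*not* emulate: GA's 17-day albumin turnover kinetics (GA is a
regression-style link, because only the correlation structure matters
for pipeline testing), sensor drift and calibration error, treatment
effects on the trace, and any joint-distribution features beyond the
documented couplings. Passing recovery tests on these cohorts therefore
demonstrates that the *pipeline* recovers a known structure — not that
the indices perform at any particular level in real patients.

Setting both couplings to zero (and equalising the per-type $v$
targets) gives a null generator used to check that the screening,
stepwise selection and cutoff sweep do not manufacture associations.

## Numerical and design choices

* Unit conversion constant: 18.016 mg/dl per mmol/l, exact round-trip.
* All SDs share one `sd_ddof` (default 1, sample SD).
* Sweep ties break toward the lower SD threshold; Youden ties toward
  the more sensitive cutoff; both deterministic.
* AUC confidence intervals: Hanley–McNeil (clipped to [0, 1]); the
  p-value is a normal-approximation test of AUC = 0.5.
* Degenerate inputs error by name (constant sample for the normality
  test, single-class labels for ROC, sub-48-h traces for MODD) except
  where a flagged result is the scientifically correct answer (MAGE
  with no qualifying excursion; combined analysis with an empty
  definite group).
* Reproducibility: `generate_cohort()` is bit-identical under a fixed
  seed and restores the caller's RNG state.

Problem sizes used by the validation suite — oracle equivalence on 110
random traces of 60–600 samples, 1000 random ROC instances, 100 seeded
100-subject recovery cohorts, 200-replicate null calibrations — were
chosen so the whole suite runs in a couple of minutes on one CPU while
keeping Monte-Carlo bounds comfortably away from their thresholds.

## Limitations

The serial-cutoff sweep is a data-dredging procedure by construction;
the package quantifies its optimism but a cutoff chosen this way still
requires external validation. The combined-criterion ROC construction
is one of several defensible readings of a two-rule classifier. The
generator's couplings are linear; real GA/variability relationships are
unlikely to be. MODD is computed as plain 24-h alignment without any
standardisation of daily conditions, which is all a free-living CGM
trace permits.
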