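---
title: "Evaluating indirect tests for failure of passive immunity transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating indirect tests for failure of passive immunity transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftpidta)
```

## The problem

Newborn calves acquire circulating immunoglobulin from colostrum rather than
in utero. When absorption fails — failure of transfer of passive immunity
(FTPI), conventionally serum IgG < 10 g/L in the first week of life — the
calf faces sharply elevated risks of septicaemia, diarrhoea and respiratory
disease. The reference measurement, radial immunodiffusion (RID), takes a
day and a laboratory; practice relies on indirect serum proxies measured
calf-side: total protein by biochemistry analyzer (`stp_ba`, g/L) or optical
refractometer (`stp_op`, g/L), digital Brix refractometry (`brix`, %),
calculated globulin (`glob = stp_ba - alb`, g/L) and γ-glutamyl transferase
activity (`ggt`, IU/L), an enzyme abundant in colostrum whose serum activity
falls steeply with age.

`ftpidta` evaluates such a panel against the RID reference on a cohort of
calves sampled at 2–6 days of age. The fitting function `ftpi_eval()`
returns a classed object carrying, per test: the test–IgG Pearson
correlation, the empirical ROC curve, the Youden-optimal cutoff with exact
binomial confidence intervals, corner distance, AUC and Cohen's kappa, and a
pair of confidence-constrained decision thresholds with an explicit grey
zone.

## The statistical procedure

**Reference classification.** A calf is FTPI-positive iff `igg_rid <`
threshold (strict inequality; default 10 g/L, with 8 g/L supported). Calves
younger than 2 d (absorption incomplete), older than 6 d (IgG catabolism and
endogenous synthesis) or of unknown age are excluded before analysis.

**ROC construction.** All five proxies *decrease* with FTPI, so every curve
uses the lower-tail convention: call positive iff value ≤ cutoff. Candidate
cutoffs are the distinct observed values plus a sentinel for the
all-negative rule, so the curve runs from (0, 0) to (1, 1). Reported
cutoffs are observed values on the instrument's own scale, not inter-value
midpoints — a deliberate choice so that thresholds are directly usable on a
refractometer or analyzer readout. Orientation is a modelling statement:
a curve whose AUC falls below 0.5 is rejected with an error rather than
silently flipped (`check_direction = FALSE` overrides).

**Cutoff selection.** The primary criterion is Youden's
\(J = Se + Sp - 1\). The paper-trail statistics at the selected point are
the corner distance \(d = \sqrt{(1-Se)^2 + (1-Sp)^2}\) (both \(d\) and
\(d^2\) are reported, since the two appear interchangeably in the applied
literature), the trapezoidal AUC (equal to the Mann–Whitney pairwise
probability with ties counted half), and unweighted Cohen's kappa of the
dichotomized test against the reference. Ties on \(J\) are broken by
smaller \(d\), then higher sensitivity, then smaller cutoff — deterministic
and documented, because the maximizer is frequently non-unique on real
data.

**Constrained thresholds.** For field decisions one often wants ≥95%
confidence in a call. The rule-in cutoff maximizes sensitivity subject to
specificity ≥ `constrained_sp`; the rule-out cutoff maximizes specificity
subject to sensitivity ≥ `constrained_se`. Values between the two fall in a
grey zone where no confident call is made. A side satisfiable only by the
degenerate never-call rule is reported `NA` with a message.

**Uncertainty.** All proportion intervals are exact Clopper–Pearson
(beta-quantile form), the defining property being coverage at least nominal
for every true proportion. Paired comparisons of two tests use the exact
McNemar binomial test on discordant calls (doubling the smaller tail,
capped at 1), computed separately within reference-positive calves
(sensitivity comparison) and reference-negative calves (specificity
comparison).

**Design statistics.** `sample_size_prop()` implements
\(n = \lceil z^2 p(1-p)/d^2 \rceil\) with the exact normal quantile
(1.959964 at 95%), and `total_sample_size()` scales a per-class requirement
by an anticipated prevalence; at \(p = 0.8\), ±10% precision, 95%
confidence and 25% prevalence these give 62 and 248. `intra_assay_cv()`
summarises replicate repeatability as per-sample SD/mean.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `ftpi_threshold` | 10.0 | g/L IgG | reference positivity (strict `<`); 8.0 is the common alternative |
| `conf_level` | 0.95 | — | level of all exact binomial intervals |
| `constrained_sp`, `constrained_se` | 0.95 | — | rule-in / rule-out constraints |
| `age_window` | [2, 6] | days | inclusive inclusion window |
| `ggt_strata` | 2–3 d, 4–6 d | days | GGT age stratification |
| `borderline_exclusion` | off | g/L | closed IgG interval discarded in the sensitivity analysis |

## What the synthetic generator emulates

Field datasets of this kind are rarely deposited, so the package carries a
generator (`synth_config()` / `synth_cohort()`) reproducing the statistical
structure the analysis assumes, and the test suite runs entirely on it.

* **IgG marginal**: a single log-normal moment-matched to mean 16.26 / SD
  8.91 g/L (`sdlog` ≈ 0.5125, `meanlog` ≈ 2.657), implying an FTPI
  prevalence of about 24% at 10 g/L.
* **Linear tests**: each proxy is `intercept + slope·IgG + noise` with
  `slope = r·sd_test/sd_IgG`, `noise_sd = sd_test·sqrt(1 − r²)`, hitting
  the marginal mean/SD and the test–IgG correlation (0.73 Brix, 0.74
  optical protein, 0.87 analyzer protein) exactly in expectation. The
  correlations are linear-scale quantities, which is why calibration is in
  IgG rather than log-IgG.
* **Albumin and globulin**: albumin shares a component with the
  analyzer-protein noise; its loadings are solved in closed form so that
  albumin's mean/SD (22.24 / 3.21), globulin's SD (7.84) and the
  globulin–IgG correlation (0.89) are all exact. This constraint set leaves
  no freedom for the albumin–total-protein correlation, which emerges at
  about 0.49 (observed field values are nearer 0.6): the full printed
  correlation matrix is not jointly attainable under a linear-Gaussian
  model with these marginals, and the generator prioritises the marginals
  and the five test–IgG correlations that the recovery tests check.
* **GGT**: generated within age group (means 640.46 / 456.56 IU/L for
  2–3 d / 4–6 d). Because the between-group mean shift dilutes the pooled
  correlation, the within-group correlation is inflated analytically so the
  pooled target (0.67) is met. GGT is physically non-negative, so draws are
  left-censored at zero (~3% under this calibration); each group's
  intercept and noise SD are re-solved by quadrature over the IgG marginal
  so the *censored* moments match the targets, and the within-group
  correlation is rescaled for the censoring attenuation.
* **Cohort structure**: age classes (including the day-0/1, over-6-day and
  missing-age calves the filter removes) are allocated by largest-remainder
  apportionment, so the default 258-calf cohort reproduces the 132/113/3/3/7
  composition exactly; herds hold 1–6 calves (median 3); an optional herd
  effect (`herd_sd`, log-IgG scale) defaults to 0 because the analysis
  ignores clustering.
* **Missingness**: completely at random per test, calibrated to the
  observed per-test sample sizes — except GGT, whose missingness differs by
  age group to match the published stratum sizes (114 of 132 and 86 of 113
  observed), which also pins the pooled GGT mean.

**What it does not emulate.** Conditional distributions in real serum
panels are skewed and heteroscedastic, not Gaussian; missingness in the
field is unlikely to be completely at random; inter-operator and
inter-instrument variation (15 practitioners, several refractometer brands)
is absent; and the log-normal's implied quartiles (≈10.1 / 20.2 g/L) are
narrower than observed IgG quartiles (8.80 / 22.70), a sign that real
cohorts mix distinct FTPI+/FTPI− subpopulations — an optional two-component
mixture (`igg_mixture`) is provided for that, off by default since the
single log-normal meets every stated calibration tolerance. A consequence
worth stating plainly: cohorts drawn from this generator yield *lower*
diagnostic performance (J around 0.55–0.6 for the best tests) than the
field study the calibration targets came from, because a bivariate Gaussian
with r = 0.87–0.89 simply cannot produce J ≈ 0.7–0.8. Passing recovery
tests therefore demonstrate that the pipeline measures correctly on a known
truth — not that any test will achieve a particular accuracy in the field.

## Numerical choices

* Quartiles use linear interpolation between order statistics (R type 7),
  exposed rather than hard-coded, since reported field tables seldom state
  their convention.
* Missing tokens in CSVs: empty cells, `NA`, `NaN` (case-insensitive) are
  silently missing; any other non-numeric token is missing *with a
  warning*; structural faults (duplicate herd/calf keys, negative
  measurements, Brix outside (0, 30)%) are errors.
* The CSV writer emits 17 significant digits so write/read round-trips are
  bit-exact.
* The borderline sensitivity analysis treats its interval as closed
  ([9, 11] g/L by default) and re-evaluates the *frozen* main-run cutoffs
  rather than re-optimizing, so its deltas isolate the effect of
  reference-assay imprecision near the threshold.
* The GGT age contrast uses a rank-sum (Mann–Whitney) test: the two age
  groups are independent samples, so a signed-rank test — which requires
  pairing — would be mis-specified; exact enumeration is used when both
  groups have ≤ 10 observations and no ties.
* Generator quadrature: Simpson's rule on 401 nodes over ±8 SD of the
  log-IgG scale; censored-moment solves use Nelder–Mead to a 1e-14 relative
  tolerance and the correlation rescaling iterates to 1e-9.

## Problem sizes in the test suite

Structural and oracle tests run on cohorts of tens to hundreds of calves
and exhaustive small instances (all binomial pairs with n ≤ 25, all
discordant splits to 10+10, random ROC instances up to 30 records).
Calibration-recovery and convergence tests use one 10,000-calf cohort:
large enough that three Monte-Carlo standard errors separate a correct
implementation from a miscalibrated one, small enough to run in seconds.

## Known limitations

* Complete-case analysis per test, as in the motivating design; no
  imputation. The per-test `n` is always reported.
* No smoothed/binormal ROC, no partial AUC, no bootstrap AUC intervals.
* No latent-class correction for an imperfect reference: the RID assay is
  treated as truth, with the borderline-exclusion analysis as the available
  robustness probe.
* No herd-level mixed modelling; the generator's herd effect exists only to
  probe robustness of the pooled analysis.
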