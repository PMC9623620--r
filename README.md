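# ftpidta

Diagnostic test accuracy for **failure of transfer of passive immunity
(FTPI)** in neonatal calves.

Calves are born essentially agammaglobulinemic and depend on colostral IgG;
FTPI — conventionally serum IgG < 10 g/L, against a radial-immunodiffusion
(RID) reference — raises mortality and disease risk and remains common in
beef and dairy herds. Because RID is slow and laboratory-bound, practice
relies on indirect serum proxies: total protein by biochemistry analyzer
(STP_BA) or optical refractometer (STP_OP), digital Brix (%), calculated
globulin (GLOB = STP_BA − ALB) and γ-glutamyl transferase activity (GGT,
strongly age-dependent). This package evaluates such a panel against the
RID reference and ships a calibrated synthetic cohort generator so the full
pipeline is testable without field data.

For each test, on its own complete cases, `ftpi_eval()` computes:

- the empirical ROC curve (lower-tail convention: value ≤ cutoff ⇒ FTPI+)
  and its trapezoidal AUC = P(value₊ < value₋) + ½·P(tie);
- the Youden-optimal cutoff, J = Se + Sp − 1, with the corner distance
  d = √((1−Se)² + (1−Sp)²) and d²;
- exact Clopper–Pearson 95% intervals for Se and Sp, and Cohen's κ against
  the reference classification;
- rule-in / rule-out thresholds: best Se subject to Sp ≥ 95%, best Sp
  subject to Se ≥ 95%, with the grey zone in between;
- test–IgG Pearson correlations, GGT age-stratified analyses, exact McNemar
  paired test comparisons, a borderline-IgG exclusion sensitivity analysis,
  sample-size planning (⌈z²p(1−p)/d²⌉) and intra-assay CV summaries.

## Worked example

```r
library(ftpidta)

cohort <- synth_cohort(synth_config(seed = 42))   # 258 synthetic calves
fit <- ftpi_eval(cohort)                          # age filter -> 245 analysed
fit
#> FTPI diagnostic test evaluation
#>   245 calves analysed (of 258 input), FTPI prevalence 25.3% (62/245) at IgG < 10 g/L
#>
#> Youden-optimal cutoffs:
#>       test     cutoff                se                sp    J dist  AUC kappa
#>     stp_op  52.448671 64.5% (51.3-76.3) 75.8% (68.9-81.9) 0.40 0.43 0.77  0.36
#>       brix   8.867154 96.2% (87.0-99.5) 50.0% (41.7-58.3) 0.46 0.50 0.78  0.32
#>     stp_ba  54.942249 80.6% (68.6-89.6) 76.9% (70.1-82.8) 0.58 0.30 0.83  0.50
#>       glob  32.568377 79.0% (66.8-88.3) 80.8% (74.3-86.2) 0.60 0.28 0.86  0.54
#>        ggt 361.596657 49.1% (35.4-62.9) 81.1% (73.8-87.0) 0.30 0.54 0.69  0.30
#>  ggt_2-3 d 697.695407 90.9% (75.7-98.1) 47.0% (35.9-58.3) 0.38 0.54 0.72  0.28
#>  ggt_4-6 d 384.661004 63.6% (40.7-82.8) 70.8% (58.2-81.4) 0.34 0.47 0.68  0.30
```

Each row is one test: its optimal cutoff on the instrument's own scale,
sensitivity and specificity with exact 95% intervals, Youden's J, the
distance to the perfect-test corner of ROC space, AUC, and chance-corrected
agreement with the RID classification. GGT appears three times because its
optimal cutoff shifts with age. `summary(fit)` adds descriptive,
correlation, constrained-threshold and sensitivity-analysis tables;
`coef(fit)` returns the cutoffs; `predict(fit, newdata)` classifies new
calves (with `rule = "constrained"`, as positive / grey / negative);
`plot(fit)` draws the ROC curves; `write_report(fit, dir)` serializes
everything to JSON and CSV.

```r
sample_size_prop(0.80, 0.10, 0.95)   # 62 calves per reference class
total_sample_size(62, 0.25)          # 248 total at 25% expected prevalence

cmp <- compare_tests_paired(fit, "brix", "stp_op")
c(cmp$p_se, cmp$p_sp)                # exact McNemar p-values, Se and Sp
```

A thin command-line front end (`inst/scripts/ftpi-dta.R`) exposes
`simulate`, `analyze`, `compare`, `samplesize` and `cv` subcommands over
the same functions.

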