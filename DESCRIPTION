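Package: ftpidta
Title: Diagnostic Test Accuracy for Failure of Passive Immunity Transfer in Calves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the parallel evaluation of indirect serum tests for
    failure of transfer of passive immunity (FTPI) in neonatal calves against
    a radial-immunodiffusion IgG reference standard. Provides empirical ROC
    construction with Youden-index and corner-distance optimal cutoffs,
    sensitivity and specificity with exact (Clopper-Pearson) binomial
    confidence intervals, trapezoidal AUC, Cohen's kappa, specificity- and
    sensitivity-constrained rule-in/rule-out thresholds with an explicit grey
    zone, exact McNemar paired comparisons, sample-size planning for
    proportion estimates, intra-assay coefficient-of-variation summaries, and
    a calibrated synthetic cohort generator that emulates the joint
    distribution of serum IgG and five indirect measurements (total protein
    by analyzer and optical refractometer, digital Brix, calculated globulin,
    and age-dependent gamma-glutamyl transferase activity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse,
    yaml
Config/testthat/edition: 3
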