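Package: n3grs
Title: Genetic Risk Scores for the Triglyceride Response to Omega-3 Supplementation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nutrigenetic analysis of plasma triglyceride (TG)
    responsiveness in crossover supplementation trials of marine omega-3
    fatty acids (EPA and DHA). Implements genotype quality control (minor
    allele frequencies, Hardy-Weinberg equilibrium chi-squared filtering,
    allele-count frequency comparisons between cohorts or responder
    subgroups), construction of a signed unit-weight rare-allele genetic
    risk score, classification of participants into ordered responder
    subgroups (responder, non-responder, adverse responder) using an
    intra-individual variability window, and covariate-adjusted ordinal
    (proportional-odds) and binary logistic models of responder class on
    the score, with predicted-probability curves and delta-method
    confidence bands. A synthetic-data generator reproduces the
    statistical structure the analysis assumes so every stage is testable
    without participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
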