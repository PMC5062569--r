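Package: AncestryBias
Title: Auditing Ancestry-Related Bias in Clinical Variant Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify ancestry-related bias in clinical variant
    prioritization. Classifies single-nucleotide variants into clinical
    priority classes (pathogenic-annotated versus non-annotated, deleterious
    versus non-deleterious) under configurable minor-allele-frequency and
    in-silico-predictor filters, correlates per-individual class counts with
    African-ancestry proportions using population-structure-aware pooled
    (Fisher-z, sample-size weighted) correlations, tracks that correlation
    across versioned pathogenicity-database releases with sign-flip detection
    and driver-variant attribution, and translates class counts into
    per-patient confirmation-cost estimates. Ships a seeded synthetic-data
    generator for admixed cohorts with planted ancestry biases so the whole
    audit is exercisable end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
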