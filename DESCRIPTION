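Package: immunorank
Title: Reference-Cohort Percentile Ranking and Association Analysis for
    Targeted Immune Transcript Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes raw read counts from targeted immune RNA panels to
    normalized reads per million (nRPM) via no-template-control background
    subtraction and housekeeping-gene median-ratio scaling, converts nRPM to
    percentile ranks against a locked reference cohort, and classifies genes
    as low/moderate/high expressed. Downstream analyses cover a complete
    pan-cancer immune profiling workflow: per-cancer-type expression
    landscapes, agonist-candidate (receptor-high/ligand-low) profiling,
    univariable and multiply-imputed multivariable logistic association
    screens, empirical-Bayes moderated-t differential expression,
    Fisher-exact somatic-mutation enrichment at gene and hallmark-pathway
    level with Benjamini-Hochberg q-values, and Kaplan-Meier/Cox survival
    models stratified by transcript rank. A seeded synthetic-cohort
    generator supplies realistic fixtures so the whole pipeline is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    limma,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
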