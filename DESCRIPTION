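Package: mrmblup
Title: Metagenome and Genomic Relationship Matrices for Kernel REML
    Analysis of Methane Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free profiling of rumen metagenome community (RMC)
    sequence tags, construction of metagenome (MRM) and genomic (GRM)
    relationship matrices, restricted maximum likelihood (REML) estimation
    of heritability and microbiability with kernel mixed models, BLUP
    prediction with forward and cohort-blocked cross-validation, a
    bivariate proxy-trait model yielding genetic and phenotypic
    correlations with delta-method standard errors, and the relative
    efficacy of indirect selection.  Includes a synthetic-data generator
    with known genetic, microbial, cohort, lot and sequencing-depth
    structure so the whole pipeline can be exercised end-to-end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
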