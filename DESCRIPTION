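Package: famvarsel
Title: Family-Based Prioritization of Low-Frequency Moderately Penetrant Risk Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disease-model-based prioritization of low-frequency, moderately
    penetrant risk variants from whole-exome sequence data of high-risk
    families, with case-control validation statistics. Implements pedigree
    kinship and relative-selection utilities, a population-frequency and
    protein-impact filtering cascade with a proband frequency-ratio
    enrichment statistic, haplotype-based minimum/maximum affected-carrier
    frequency bounds averaged across carrier families, multi-criterion
    candidate selection, post-genotyping quality control, and the
    validation arm: dominant-model logistic regression, Fisher's exact
    tests, polytomous regression by disease aggressiveness, fixed-effect
    inverse-variance meta-analysis, a risk-allele count score, and a
    variant co-occurrence test. Seeded generators for synthetic pedigrees,
    gene-dropped haplotypes, planted risk variants and case-control
    cohorts make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    nnet,
    metafor,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
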