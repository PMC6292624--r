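Package: mitocline
Title: Spatio-Temporal Analysis of mtDNA Haplogroup Structure in Birth Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mitochondrial DNA haplogroup structure in
    large array-typed birth cohorts: haploid genotype calling from normalized
    array intensities (Norm R / Norm Theta) with sample-level call-rate QC,
    hierarchical haplogroup classification against a tree of defining SNPs,
    median-joining haplotype networks with star-contraction preprocessing and
    maximum-parsimony post-processing, principal-component summaries of
    haplogroup structure, and spatio-temporal frequency statistics (exact and
    permutation Fisher tests, Bonferroni correction, yearly trend series).
    Includes a synthetic-cohort generator emulating regional clines and
    immigration-driven temporal trends so the full pipeline is testable
    without registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr
Config/testthat/edition: 3
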