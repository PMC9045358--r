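Package: mgscohort
Title: Metagenomic Species Quantification and Cohort Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for shotgun-metagenomics cohort studies of
    the gut microbiome: quality-based read-pair filtering and gene-catalog
    mapping acceptance rules, core-gene quantification of metagenomic species
    (MGS) with a minimum core-gene detection rule, rarefaction, alpha
    diversity (species richness, Shannon index), compositional beta diversity
    (centered log-ratio transform, Aitchison distance, permutation PERMANOVA),
    a univariate association battery (Spearman, Mann-Whitney, quartile
    contrasts) with family-wise multiple-testing correction, a simplified
    negative-binomial differential-abundance test against continuous serum
    markers, and KEGG-module functional aggregation with prevalence
    filtering. Ships a synthetic cohort generator that emulates an
    overweight/obese pregnancy cohort (diet-quality scores, glucose-metabolism
    and inflammation markers) with configurable injected effects, so every
    analysis stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
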