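Package: epiprs
Title: SNP-SNP Interaction Detection, Polygenic Risk Scores, and
    Gene-Environment Interaction Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for case-control statistical genetics
    built around generalized multifactor dimensionality reduction (GMDR):
    genotype quality control (missingness, heterozygosity, Hardy-Weinberg
    equilibrium by chi-square or exact test), covariate-adjusted single-SNP
    logistic association, linkage-disequilibrium pruning with EM haplotype
    r-squared, exhaustive cross-validated GMDR search for the best
    multi-locus interaction model, unweighted risk-allele polygenic risk
    scores (PRS) with categorical grouping, stratified and interaction-term
    PRS-by-lifestyle analysis, and dietary-pattern extraction from
    food-frequency data by principal component analysis with varimax
    rotation. Includes a cohort simulator (Hardy-Weinberg genotypes,
    two-locus LD, planted epistatic penetrance, covariate and
    PRS-by-diet effects, latent-factor food intakes) so every stage is
    testable without access to restricted cohort data, plus readers and
    writers for PLINK bed/bim/fam and VCF genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
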