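Package: dnamvar
Title: Variance Partitioning of Complex Traits with Genome-Wide DNA
    Methylation and Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian variance partitioning of a quantitative trait
    between genome-wide DNA methylation probes and SNP genotypes. Implements
    a Gibbs sampler for whole-genome penalised regression with a spike at
    zero plus a mixture of normal effect-size classes fitted over multiple
    marker sets, reporting per-set variance fractions with credible
    intervals, per-marker posterior inclusion probabilities and
    effect-size-class architecture tables. Companion tools cover
    restricted-maximum-likelihood variance components on omics and genomic
    relationship matrices (including a bivariate cross-sex decomposition),
    construction and out-of-sample evaluation of methylation profile
    scores, a phenome-wide association stage with Bonferroni control, a
    synthetic-cohort generator with known ground truth, and readers and
    writers for the tabular and PLINK formats involved.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
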