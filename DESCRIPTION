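Package: cwas
Title: Cell-Type Wide Association Studies from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether genetically regulated cell-type proportions (GRPs)
    are associated with complex traits using only GWAS summary statistics.
    Tissue-level gene expression is imputed from cis-SNP elastic-net weights,
    deconvolved against a gene-by-cell-type signature matrix into GRPs, and a
    burden-style z statistic combines per-SNP GWAS z-scores with the
    deconvolution weights, normalised by reference-panel genotype and GRP
    standard deviations. Includes elastic-net weight training with
    cross-validated accuracy filters, signature-matrix curation from labelled
    single-cell expression, cross-trait and cross-tissue association
    correlation analyses, a binomial cell-type enrichment test, and a fully
    synthetic simulation harness (LD-structured genotypes, sparse cis
    weights, signature matrices, phenotypes with controlled GRP heritability)
    for power and type-I-error calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    Matrix,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
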