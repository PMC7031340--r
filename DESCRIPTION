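Package: decoqtl
Title: Cell-Type Deconvolution, Interaction eQTL Mapping and Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives cell-type signature genes from labeled single-cell
    RNA-seq (including cross-species ortholog transfer), estimates cell-type
    compositions of bulk RNA-seq samples with a support-vector-regression
    deconvolution core and permutation p-values, maps cis-eQTLs with linear
    mixed models using compositions as covariates, tests genotype-by-cell-type
    interactions to call cell-type-associated and cell-type-specific eGenes,
    and colocalizes eQTL and GWAS signals via approximate Bayes factor
    posteriors with threshold-scan enrichment. A synthetic-data module
    generates every input with known ground truth so the whole chain is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    lme4,
    Matrix,
    pracma,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
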