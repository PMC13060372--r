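Package: microchimr
Title: Detection of Rare Foreign-Genotype Cells in Single-Cell RNA-Seq Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies exceedingly rare cells of foreign genotype (microchimerism,
    post-transplant measurable residual disease) in single-cell RNA-seq data from
    per-cell reference/alternative allele UMI counts at common variant loci.
    Fits per-locus beta-binomial models of the majority genotype, scores cells by
    coverage-normalized log-likelihood, flags anomalies by robust z-score,
    iteratively removes their counts until the anomalous set converges, and makes
    final majority/minority calls by posterior probability under two fitted model
    sets. Includes a pedigree-aware synthetic chimeric-mixture simulator
    (unrelated, parent/child, sibling genotypes) with known ground truth, a
    likelihood-separation score for arbitrating against external clustering
    assignments, and readers/writers for vartrix-style VCF + barcode +
    MatrixMarket inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
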