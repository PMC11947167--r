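Package: twasprio
Title: Transcriptome-Wide Association Gene Prioritization from GWAS Summary Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A multi-stage pipeline for prioritizing candidate susceptibility
    genes from GWAS summary statistics and eQTL-derived expression prediction
    models. Implements the summary-based TWAS correlation test with
    LD-reference allele harmonization, a weight-resampling permutation test
    conditional on GWAS effects, locus-wise forward-stepwise joint-conditional
    fine-mapping of correlated gene signals, approximate-Bayes-factor
    colocalization of eQTL and GWAS signals, SNP-level GWAS conditioning on
    predicted-expression effects, and a median-expression permutation
    enrichment test. A synthetic-data generator emulates block-structured LD
    reference panels, sparse cis-SNP weight models, GWAS Z-scores under a
    mediated causal-gene model, and single-cell or bulk expression matrices
    with planted ground truth, so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, GenomeWideAssociation, SNP, StatisticalMethod
RoxygenNote: 7.3.3
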