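Package: nephroclust
Title: Soft Clustering of Kidney-Function GWAS Variants with NMF and
    Cluster-Specific Polygenic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deconstructs the genetic heterogeneity of chronic kidney
    disease (CKD) from published GWAS summary records. Builds a
    non-negative trait-by-variant association matrix from lead variants,
    their linkage-disequilibrium proxies and GWAS-catalog style
    association records; soft-clusters it with multiplicative-update
    non-negative matrix factorization (NMF) and a Bayesian NMF with
    automatic relevance determination as a cross-check; derives
    cluster-specific polygenic scores (cPGS) on genotype dosages; and
    validates clusters with a phenome-wide association study (PheWAS)
    harness including Phecode case/control construction, plus preranked
    gene-set enrichment and hypergeometric overrepresentation analysis.
    A synthetic-data generator with planted cluster structure emulates
    every pipeline input so the full workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    nortest,
    randomForest,
    jsonlite
Suggests:
    fgsea,
    vcfR,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
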