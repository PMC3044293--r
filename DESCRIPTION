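Package: probic
Title: Query-Based Probabilistic Biclustering of Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Query-based biclustering of gene expression compendia. A bicluster
    is modelled as a set of per-array Normal distributions with conjugate
    Normal-Inverse-Chi-Squared priors centred on the mean expression profile of
    a user-supplied seed (query) gene set, and is learned by hard-assignment EM
    against per-array background distributions estimated robustly up front by
    symmetric trimming. Includes bicluster expression-quality statistics
    (STD-within, STD-across), categorization of results against true and noisy
    seed genes, one-sided hypergeometric mid-P enrichment of bicluster genes
    against annotation sets, a synthetic-data generator with implanted
    constant-column biclusters for benchmarking, and command-style drivers for
    noisy-seed robustness and cross-validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
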