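Package: grnscape
Title: Bootstrap-Ensemble Mutual-Information Gene Regulatory Networks and
    Their Functional Landscape
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers gene regulatory networks from expression data by
    bootstrap aggregation of conservative maximum-mutual-information
    networks (the bagged C3NET scheme), with mutual information estimated
    from Pearson correlation under a bivariate-Gaussian model. Provides the
    surrounding analysis toolkit: microarray-style quantile normalization
    and probe-to-gene collapsing, network topology summaries with a
    discrete maximum-likelihood power-law fit of the degree distribution,
    gene-pair enrichment analysis (GPEA) of annotation terms by a
    hypergeometric test on edges, census-cancer-gene landscape statistics
    (neighborhood subnetworks, shortest-path tables, an empirical closeness
    test, shortest-path-union degree rankings), and a gene-label
    permutation test for chromosome-pair interaction enrichment. A
    synthetic-data generator produces planted networks, correlated
    expression, annotations, chromosome catalogs and census gene lists so
    the whole pipeline can be exercised and calibrated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
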