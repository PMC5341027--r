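Package: ibclust
Title: Individual-Based Clustering of Movement Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters individuals by the locations they visit using a Bayesian
    multinomial mixture with a truncated stick-breaking prior, so that the
    number of groups emerges from the data rather than being fixed in advance.
    The model is fit with a blocked Gibbs sampler. Includes tools to detect
    mixed-membership (critical connectivity) sites, refit visitation profiles
    for a later time window with group memberships frozen, test for temporal
    changes in visitation via posterior credible intervals, estimate origin
    shares of visitors, and generate synthetic movement-network benchmarks
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    igraph,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
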