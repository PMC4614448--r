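Package: mhvg
Title: Multiplex Horizontal Visibility Graph Analysis of Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps each channel of a multivariate time series to its horizontal
    visibility graph (HVG) and analyses the resulting multiplex network.
    Provides the two headline multiplex descriptors -- average edge overlap and
    interlayer degree mutual information -- together with the weighted graph of
    layers and its backbone and maximum-spanning-tree summaries. Includes a
    coupled-map-lattice simulator (diffusive ring/chain and globally coupled
    mean-field variants of the fully chaotic logistic map) as a validation
    substrate, a fixed-partition symbolic mutual-information baseline, and
    windowed (temporal multiplex) analysis for long nonstationary recordings.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
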