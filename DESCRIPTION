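Package: heatshockr
Title: Gaussian-Mixture Analysis of Heat-Shock Expression and HSF1 Promoter Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing heat-shock transcriptional
    responses together with HSF1 promoter occupancy measured on tiling
    microarrays. Expression noise thresholds are estimated by fitting
    one-dimensional Gaussian mixtures to log2 signal distributions and reading
    off the posterior crossover of the lowest (noise) component; differential
    expression is called by fitting a Gaussian mixture to the per-gene signal
    log ratio (SLR) distribution; response profiles are clustered with
    multivariate Gaussian-mixture models; gene sets are tested with a
    conditional hypergeometric over-representation test on a term DAG.
    Promoter binding is called from probe-level antibody/mock (AB1/AB0)
    intensities via quantile normalization, percentile background subtraction,
    a signed-rank enhancement test, a permutation non-uniformity test, and
    Benjamini-Hochberg FDR control. A synthetic-data generator with known
    ground truth emulates the data structure end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    mclust,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
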