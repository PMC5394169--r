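Package: hopscape
Title: Hopfield Attractor Landscapes of Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models disease progression from staged gene-expression profiles
    as relaxation on a Hopfield energy landscape. The network is trained
    non-parametrically from pairwise Pearson correlations between genes;
    samples relax under synchronous sign-update dynamics to fixed-point
    attractors interpreted as normal and disease cell states. Provides
    estimators for attractor width (standardized intra-group distance) and
    depth (energy drop to the attractor), robustness analysis by random
    perturbation of correlation edges, stage-specific significance-filtered
    correlation networks with common/unique edge decomposition, landscape
    visualisation over a principal-component grid, and a synthetic-data
    generator with planted co-expression programs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    mgcv,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
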