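Package: rmtnet
Title: Gene Co-Expression Networks by Random Matrix Theory Thresholding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs gene co-expression networks from expression
    matrices by building all-pairs Pearson similarity matrices, selecting a
    signal/noise correlation cutoff where the nearest-neighbour spacing
    distribution of the pruned matrix's eigenvalues transitions from
    Poisson towards the Gaussian orthogonal ensemble, and extracting the
    thresholded edge list.  Includes overlapping module detection by link
    communities, hypergeometric term enrichment, Cohen's kappa functional
    comparison of module profiles, a sample/probe-set perturbation harness
    for network robustness studies, and a synthetic-data generator with
    planted co-expression modules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
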