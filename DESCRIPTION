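Package: snvnet
Title: Subnetwork-Voting Construction and Analysis of Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary functional connectivity networks from regional
    time courses by the classic full-length Pearson correlation method and by
    a sliding-window subnetwork-voting (SNV) method, thresholds them to an
    exact proportional edge density, computes five topological properties
    (global efficiency, mean clustering coefficient, transfer coefficient,
    small-world value, long-edge count), compares two groups across a density
    grid with pooled t-tests, Benjamini-Hochberg FDR control and sign-flip
    permutation tests, and classifies subjects with a linear support vector
    machine under paired K-fold cross-validation.  A seeded synthetic-cohort
    generator with planted ground-truth networks and nonstationary noise
    bursts makes the full pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
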