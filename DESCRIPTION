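Package: cambronet
Title: Interaction Network Inference from Stratigraphic Fossil Abundance Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers trophic and competitive interaction networks from
    stratigraphic fossil abundance tables. Detects biofacies boundaries by
    SHE-based biozone identification and ANOSIM, builds shrinkage-regularized
    partial correlation networks within sub-assemblages and running
    stratigraphic windows, quantifies trait-linked preservation bias with an
    ERGM-and-Hamming-distance coefficient calibrated on an agent-based
    resource-prey-predator simulator, decomposes correlation distributions
    into Gaussian components clustered into interaction categories by spectral
    analysis with the gap statistic, and extracts majority-rule consensus
    interactions for comparison with literature-proposed interactions. A
    synthetic assemblage generator with planted interaction structure,
    planted facies boundaries and trait-dependent binomial preservation
    thinning provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
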