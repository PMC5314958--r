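Package: protgrad
Title: Gradient Analysis of Protected-Area Representativeness and Its Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse what drives the spatial distribution of
    protected areas along biophysical, human, and biological gradients on a
    half-degree grid. Summarises per-cell protection into gradient histograms
    (area, protected area, and protected fraction per class), quantifies
    fraction- versus quota-representativeness with a modified Shannon
    evenness index, characterises gradient shapes with a suite of linear and
    nonlinear regression families selected by AIC, and ranks preferential
    versus opportunistic drivers with random-forest permutation importance
    tuned by out-of-bag error. Includes a synthetic-world generator with
    configurable protection regimes and covariate correlation structure so
    the whole pipeline is testable without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
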