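Package: seasonvar
Title: Temporal Variability of Community Activity Across Land-Cover Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify and decompose the temporal variability of
    community activity time series sampled along anthropogenic land-cover
    gradients. Implements harmonic-regression time-series decomposition into
    seasonal, trend and remainder components; functional variability
    (coefficient of variation) and compositional variability (Hellinger
    temporal beta diversity with species contributions); individual-based
    rarefaction of species-by-time count matrices; Loreau-De Mazancourt
    synchrony; richness estimation with Hill-number (q = 0) extrapolation;
    ordinary least-squares regression against land-cover principal-component
    scores with small-sample AICc model selection and permutation tests of
    Moran's I on residuals; and a seeded synthetic-data generator that
    emulates a multi-site biweekly trap-count monitoring design for
    ground-truth recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
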