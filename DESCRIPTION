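Package: ridge2reef
Title: Land-Sea Conservation Prioritization Under Storm Sediment Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A ridge-to-reef planning toolkit linking storm-event sediment
    runoff from island watersheds to marine reserve design. Computes
    storm-event soil loss with the modified universal soil loss equation
    (MUSLE) over curve-number runoff and D8 flow routing, disperses
    river-mouth sediment loads over a marine planning grid with a power-law
    plume model, fits a binomial generalized additive model of hard-coral
    cover against log suspended sediment with site random effects, converts
    posterior draws into per-cell probabilities of good coral condition, and
    solves minimum-set reserve selection by simulated annealing with either
    deterministic or probability-constrained representation targets. Includes
    a synthetic island-seascape generator so the whole pipeline is testable
    end to end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
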