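Package: specocc
Title: Specular Highlights and Perceived Surface Convexity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry and Bayesian ideal-observer modelling of the convexity
    bias induced by specular highlights in two-alternative forced-choice
    shape-from-shading judgements. Implements the specular-occlusion geometry
    of concave semi-ellipsoidal surfaces (bas-relief solution family, rim
    occlusion angle, feasibility boundary), a nine-parameter generative
    observer model with von Mises circular likelihoods and closed-form
    marginalization over illuminant tilt, maximum-likelihood fitting with a
    BIC model ladder, mutual-information and psychometric analyses, and
    deterministic generators for the three experimental designs together with
    seeded simulation of model observers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
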