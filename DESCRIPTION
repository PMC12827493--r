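Package: rootarch
Title: Evolution of Root System Architecture Under Below-Ground Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A functional-structural root model in which plants with explicit
    three-dimensional, segment-based root systems forage for water in a
    voxelized soil, coupled with an evolutionary algorithm that selects root
    architecture genotypes under intraspecific competition of varying
    intensity. Provides the daily soil water balance (recharge, evaporation,
    diffusion with wrap-around borders, rationed uptake), root growth driven
    by nine evolvable architecture parameters, truncation selection over
    generations, emergent root morphology metrics including the box-counting
    fractal dimension, and factorial competition experiments that quantify
    competitive effect and competitive response of the evolved species.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
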