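Package: plugflow
Title: Liquid Plug Propagation and Surfactant Delivery in Branching Airway Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates surfactant replacement therapy as the propagation of
    liquid plugs through a three-dimensional branching airway tree. A plug
    travelling along an airway deposits a trailing film on the wall following
    a capillary-number law, and splits at each bifurcation according to a
    gravity- and inertia-dependent quadratic balance parameterised by the
    local Reynolds, Bond and capillary numbers. The package provides airway
    tree readers and generators (symmetric and stochastic monopodial
    morphometry emulating the rat lung), single- and multiple-aliquot
    instillation protocols with posture sequences, and delivery-performance
    metrics: efficiency, homogeneity index, coating cost and an image-based
    quadrant homogeneity index.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
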