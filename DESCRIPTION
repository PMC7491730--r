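Package: firewoodSpread
Title: Coupled Social-Ecological Metapopulation Model of Forest Pest Spread
    via Camper-Transported Firewood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the spread of wood-boring invasive forest pests
    (such as emerald ash borer) across a network of recreational
    destinations, where long-distance dispersal is driven by campers
    transporting untreated firewood. Per-patch tree infestation dynamics
    (logistic host growth, density-dependent transmission, firewood decay)
    are coupled to replicator-dynamics social learning of the choice
    between transporting firewood and buying it locally. Includes three
    intervention levers: the net social cost of transport (public
    outreach), checkpoint interception of infested firewood, and
    time-windowed quarantine of high-betweenness patches; plus a synthetic
    gravity-model travel-network generator, k-core network reduction, and
    sweep/assessment statistics (mean cumulative infestation,
    marginal-benefit-of-outreach slope, halving interception fraction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
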