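Package: ecoefnet
Title: Eco-Efficiency of Cultivated Land Use and Its Spatial Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures city-level eco-efficiency of cultivated land utilization by
    the slacks-based measure (SBM) of efficiency with carbon emissions as the
    undesirable output, ranks frontier cities by super-efficiency SBM, builds
    directed spatial association networks from efficiency scores with a modified
    gravity model, characterizes the networks with social-network statistics
    (density, degree, closeness and betweenness centrality), partitions them
    into cohesive subgroups by CONCOR blockmodelling, and tests drivers of tie
    formation with QAP correlation and MRQAP permutation regression. Includes a
    synthetic statistical-yearbook generator with planted tie-formation effects
    for end-to-end and recovery testing, and a pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
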