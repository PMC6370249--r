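Package: gutplex
Title: Social Multiplex Dynamics of Dietary Behavior Coupled to Gut Community Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based simulator of dietary behavior on a social multiplex
    network coupled to a constraint-based gut-community metabolic model. Agents
    play an iterated Snowdrift Game with a Fermi imitation rule modulated by
    inter-layer communicability, homophily, gut metabolic similarity and
    micro-affirmation/micro-inequity biases. A feedback loop turns each agent's
    cooperation record into a happiness index that perturbs its diet; diets set
    exchange bounds of a multi-species community model solved by lexicographic
    flux balance analysis, and the resulting flux profiles drive Ward
    re-clustering of the population. Includes a toy community-model generator,
    a minimal SBML level-3 reader/writer, and post-hoc subsystem-flux
    correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    ape,
    graphics,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
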