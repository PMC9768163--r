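Package: soam
Title: Social Opinion Amplification Model on Directed Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of bounded-confidence opinion dynamics on
    directed social networks in which a fraction of agents express amplified
    versions of their true opinions. Provides directed network generators
    (Erdos-Renyi, Barabasi-Albert, scale-free, complete) with edge-list and
    GraphML serialization, the synchronous opinion-update engine with
    confidence gating, population conflict and polarization metrics, two
    polarization-countering interventions (a five-strike amplification limit
    with agent replacement, and scheduled dissemination of balanced opinions),
    and a config-driven experiment layer with replicate seeds, parameter
    sweeps, and named presets reproducing the reference experiment grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
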