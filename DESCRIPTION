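Package: pestgrid
Title: Agent-Based Simulation of Sensor-Coordinated Pest Control on a Lattice Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-hour, agent-based simulator of pest infestation and
    pesticide control in a crop field monitored by a lattice wireless sensor
    network. Bugs appear stochastically, perform clamped random walks between
    zones, eat the crop and die after cumulative pesticide exposure; each
    sensor runs a communication strategy made of a periodic hook and a
    reactive message handler. Three strategies are included (broadcast,
    neighbor warning, and a low-cost neighbor protocol that learns from past
    warnings to suppress redundant messages), together with a seeded
    replicate-experiment harness comparing strategies on electric power per
    active station, crop health, alive-bug percentage and pesticide
    consumption using Levene, Welch and Brown-Forsythe tests and Cohen's d
    effect sizes. A thin command-line interface writes per-hour evolution
    traces and comparison reports as CSV/JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
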