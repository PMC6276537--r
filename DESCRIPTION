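Package: spineLTP
Title: Simulation of Opioid-Modulated Long-Term Potentiation in a CA1 Dendritic Spine
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Biophysical simulator of pathological long-term potentiation (LTP)
    induction in a dendritic spine of a hippocampal CA1 pyramidal neuron under
    opioid modulation. Couples a passive spine membrane with kinetic AMPA and
    NMDA receptor models, an opioid-sensitive voltage-dependent Mg2+ block of
    the NMDA receptor, stochastic high-voltage-activated calcium channels with
    binomial channel opening, rapid-buffer calcium dynamics, and the bistable
    CaMKII/PP1/inhibitor-1 phosphorylation switch that drives AMPA receptor
    conductance potentiation. Provides a fixed-step forward-Euler engine with
    a compiled core, seeded reproducible stochastic runs, a five-condition
    mechanism-knockout comparison, and parameter sweeps over receptor
    conductance, calcium-channel current, and glutamate stimulus amplitude and
    frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
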