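Package: csfsim
Title: Lumped-Parameter Simulation of Craniospinal CSF Pressure and Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of cerebrospinal fluid (CSF) pressure and
    flow in the craniospinal space. Implements physiological boundary
    conditions - constant choroid-plexus production, cardiac (1 Hz) and
    respiratory (0.2 Hz) sinusoidal volume sources, and four two-element
    windkessel absorption outlets (interstitial, spinal, lymphatic,
    arachnoid villi) - on a 0D lumped intracranial pressure model used for
    compliance tuning and on a rigid multi-compartment hydraulic network.
    Provides resistance and compliance allocation across outlets, a grid
    search that fits total craniospinal compliance to a target pressure
    pulsation amplitude, monolithic and partitioned implicit outlet-coupling
    solvers, five reference case configurations, report metrics (mean
    pressures, pulsation amplitudes, flow amplitudes, outlet flow splits,
    spatial pressure differences), and YAML/CSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
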