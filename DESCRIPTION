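Package: nervestim
Title: Hybrid Electro-Neuro Modelling of Peripheral Nerve Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid volume-conductor and compartmental-axon modelling of
    electrical peripheral nerve stimulation, aimed at the design of
    intraneural (TIME) and extraneural (FINE) multichannel interfaces for
    large nerves such as the human sciatic nerve. The package generates
    anatomically plausible multi-fascicular nerve cross-sections, builds
    parametric electrode geometries, solves the quasi-static extracellular
    potential for unit active-site currents on an anisotropic heterogeneous
    finite-volume grid, simulates myelinated-fiber recruitment with the
    McIntyre-Richardson-Grill double-cable axon model, and scores electrode
    designs and stimulation policies (monopolar, bipolar, multi-implant)
    with spatial and functional fascicle-selectivity indexes, recruitment
    curves and charge thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
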