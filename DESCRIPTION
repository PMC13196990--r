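Package: neuromag
Title: Forward Simulation and Analysis of Extracellular Neural Magnetic
    Fields and Potentials
Version: 0.1.0
Authors@R:
    person("Neuromag", "Developers", email = "neuromag@example.org",
           role = c("aut", "cre"))
Description: Forward simulator and analysis toolkit for the extracellular
    electromagnetic signatures of spiking neurons. Computes magnetic fields
    from compartmental axial currents (Biot-Savart) and electrical
    potentials from transmembrane currents (line-source approximation),
    reproduces the analytic multipole scaling of cylindrical-axon current
    distributions, implements rotation-averaged spike-template similarity
    and effective-radius metrics, condition-number separability of
    channel matrices with bootstrap capacity estimation, ground-truthed
    multimodal recording generation with Poisson spike trains, and
    polarity-boundary morphology reconstruction from normal-component
    magnetic spike templates (GNBE/CNBE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    digest,
    FNN,
    quadprog
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rhdf5
Config/testthat/edition: 3
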