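Package: gaittune
Title: Experiment-Guided Tuning of Muscle-Tendon Parameters for Gait
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Hill-type muscle-tendon simulation and experiment-guided
    calibration of muscle-tendon parameters for prescribed-motion gait
    analysis. Provides the characteristic muscle curves (active and passive
    force-length, force-velocity, exponential tendon), a muscle-redundancy
    solver over a gait cycle formulated as damped Gauss-Newton least
    squares, two calibration stages (optimal fiber length, tendon slack
    length and tendon stiffness informed by normalized fiber-length traces;
    passive force-length parameters informed by passive joint moment-angle
    sweeps), a Bhargava-style metabolic-cost pipeline with whole-body
    averaging and indirect-calorimetry conversion, seeded synthetic-data
    generators for a planar leg model with known ground truth, and readers
    and writers for OpenSim storage (.sto/.mot), CSV, JSON and YAML
    parameter files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
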