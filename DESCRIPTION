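Package: sknm
Title: Cell-Based Simulation of Heterogeneous Cardiac Tissue with the
    Simplified Kirchhoff Network Model
Version: 0.1.0
Authors@R:
    person("SKNM", "Maintainers", email = "sknm@example.org", role = c("aut", "cre"))
Description: Simulates small two-dimensional collections of human ventricular
    cardiomyocytes coupled by gap junctions under the simplified Kirchhoff
    network model (SKNM). Each cell carries its own ionic membrane model (a
    hybrid O'Hara-Rudy formulation with the ten Tusscher fast sodium current),
    and cells are coupled to axial neighbours through lumped myoplasmic plus
    gap-junction conductances. Provides seeded generators for cell-to-cell
    heterogeneity (parameter scaling, constant perturbation currents,
    gap-junction variation, two-cell-type layouts), pacing protocols with
    pre-pacing and checkpointing, an adaptive Rush-Larsen integrator for the
    coupled stiff system, and biomarkers: APD50, depolarization and
    repolarization times of arrival and their dispersion, conduction velocity,
    calcium-transient amplitude and early-afterdepolarization detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
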