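Package: egressr
Title: Steered and Supervised Dynamics for Ligand Entry and Egress
    Pathways in Membrane Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates and ranks access pathways of hydrophobic ligands into
    membrane receptors on a coarse-grained model: a Langevin dynamics engine
    with Lennard-Jones and Coulomb interactions, constant-velocity steered
    pulling with a virtual spring and trapezoidal work integration,
    distance-supervised (tabu-like) unbiased entrance sampling with
    checkpoint restarts, ligand-receptor interaction-energy profiles split
    into electrostatic and van der Waals contributions, and centre-of-mass
    pose-distance tables. Ships a synthetic seven-helix ring receptor with
    configurable inter-helix gates whose ground-truth barrier ordering is
    known, so pathway-ranking claims can be tested end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
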