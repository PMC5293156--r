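Package: cryptsim
Title: Stochastic Crypt-Lattice Simulation and Clonal Analysis of
    Intestinal Cell-Fate Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-driven simulator of cell production in colonic
    crypts, modelled as a cylindrical hexagonal lattice with a stem-cell
    row undergoing neutral drift, a transit-amplifying compartment, and a
    post-mitotic differentiated compartment. Cells divide with
    exponential waiting times and displace the columns above them
    (mitotic pressure). Secretory versus absorptive fate can be committed
    early (at transit-amplifying entry), late (at differentiated-
    compartment entry), or by Delta-Notch lateral inhibition confined to
    a commitment zone; dispersive secretory-cell migration and clonal
    division synchronization are optional mechanisms. The package
    quantifies inter-crypt variability (coefficient of variation) of
    secretory-cell proportions under each mechanism and provides a
    lineage-tracing analysis pipeline: clone uniformity classification, a
    randomization null model for late commitment, bootstrap errors,
    clone-group comparisons, neutral-drift division-rate inference, and
    matching synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
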