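Package: avbmclj
Title: Aggregation-Volume-Bias Monte Carlo for Lennard-Jones Cluster
    Free Energies and Phase Coexistence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Grand-canonical cluster Monte Carlo for the Lennard-Jones
    system using aggregation-volume-bias (AVB) swap moves, in both the
    original form for liquid clusters and a lattice-based form that
    targets insertions at face-centered cubic lattice sites to sample
    solid clusters. Cluster formation free energies are obtained by
    umbrella sampling with self-adaptive biasing, and their size
    increments are fitted to the classical nucleation theory form to
    extrapolate bulk chemical potentials and surface tensions.
    Isobaric-isothermal bulk simulations supply densities, lattice
    spacings and enthalpies, from which the melting point, the
    solid-liquid coexistence line and the triple point are located via
    the Gibbs-Helmholtz and Clapeyron relations. Includes exact
    enumeration oracles that certify the acceptance rules on tiny
    lattice models, and Steinhardt bond-orientational diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
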