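Package: glycoppii
Title: Polyproline-II Conformational Analysis of Glycosylated Mucin-Domain Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the backbone conformational ensembles of
    densely O-glycosylated mucin-domain peptides, with an emphasis on the
    polyproline type II (PPII) helix. Provides an idealised backbone builder
    (internal-to-Cartesian), a desk-scale replica-exchange torsional Monte
    Carlo sampler on a basin-mixture Ramachandran potential, Boltzmann
    inversion of dihedral histograms into free-energy surfaces, secondary
    structure region classification and per-residue population tables with
    moving-block bootstrap confidence intervals, radius-of-gyration
    convergence diagnostics based on histogram overlap, and a synthetic
    dihedral-ensemble generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
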