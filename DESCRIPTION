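Package: fluxkernel
Title: Symbolic Steady-State Flux Analysis for Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the sparse kernel of a stoichiometric matrix in exact
    rational arithmetic via Gauss-Jordan elimination with researcher-selectable
    independent fluxes. Parses SBML metabolic networks, converts closed
    networks to open form, builds steady-state flux relations, cross-validates
    the exact kernel against a numerical SVD nullspace, and reduces measured
    fluxes plus irreversibility constraints to a minimal set of bounds on the
    independent fluxes via exact vertex and facet enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    jsonlite,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
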