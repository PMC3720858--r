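Package: confexplore
Title: Expansive Motion-Planning Exploration of Protein Backbone Conformations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows trees of energetically feasible protein backbone
    conformations with a density-biased expansive planner. Backbones are
    represented by phi/psi dihedral angles under idealized bond geometry;
    perturbation operators (dihedral moves, endpoint-constrained loop
    sampling via cyclic coordinate descent, rigid-body domain displacement,
    and energy minimization) are applied to weighted residue subsets defined
    by a schema, which can be generated automatically from a secondary
    structure annotation. Sampling density is estimated on a 2D grid over a
    random orthonormal projection of dihedral space, with selection biased
    towards sparse and frontier cells and acceptance gated by an energy
    threshold. Includes directed (goal-biased) and undirected search,
    transition-path analysis (per-residue torsional activity, PCA
    landscapes, basin centroids), PDB input and output, and synthetic
    hinge and multi-loop test systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
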