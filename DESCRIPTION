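Package: siteplast
Title: Functional Site Plasticity in Protein Domain Superfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps functional-site residues (catalytic, protein-protein,
    nucleic-acid and small-ligand binding) from all members of a protein
    domain superfamily onto a structurally chosen representative domain,
    and quantifies the diversity of site locations: representative
    coverage, preferential colocation across sequence subfamilies,
    structural diversity by normalised-RMSD clustering, and
    conservation-based enrichment tests. Includes a pairwise structural
    aligner (iterative superposition with dynamic programming), greedy
    sequence-identity subfamily clustering, a Valdar-style conservation
    scorer with Henikoff sequence weights, and a seeded synthetic
    superfamily generator with planted ground truth for end-to-end
    validation of every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
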