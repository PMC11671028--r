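Package: mumiscan
Title: In Silico Saturation Mutagenesis of Protein Complexes by Mutation
    and Minimization
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational deep mutational scanning of protein-protein
    complexes from a single crystal structure. Builds every single-point
    mutant by backbone-preserving template side-chain replacement, relaxes
    each mutant (solvated-box specification with a pluggable minimization
    backend and a built-in reduced-potential fallback), and scores binding
    fitness from maintained wild-type interface hydrogen bonds, geometric
    hydrogen-bond occupancies over conformational ensembles, Shrake-Rupley
    solvent accessibility (RSA), and binding-region membership statistics.
    Includes deterministic synthetic-structure generators so every analysis
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, Software
RoxygenNote: 7.3.3
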