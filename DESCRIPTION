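Package: mti
Title: Mating-Type Inference for Tetrapolar Fungi from Hybridization
    Compatibility Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the A/B mating-type allele assignment of monokaryon
    strains of tetrapolar basidiomycetes from three plain-text tables: a
    monokaryon parent table, a pairwise strain compatibility matrix from
    clamp-connection observations, and an A/B loci consistency table from
    OWE-SOJ assays on incompatible pairs. Candidate assignments are scored
    against the observations and the optimum is found by a combinatorial
    pruning traversal: a pairwise-compatible sub-population is fixed first
    and the remaining strains are resolved by an exact branch-and-bound
    over evidence-supported allele classes, returning all co-optimal
    assignments and flagging suspect records. Includes a brute-force
    set-partition oracle for verification, a synthetic population
    generator, false-positive/false-negative perturbation experiments,
    dataset summary statistics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
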