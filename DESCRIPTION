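Package: willshawcap
Title: Storage Capacity of Single-Layer Binary Associative Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the pattern-storage capacity of single-layer,
    fully connected feedforward associative networks with binary (clipped
    Hebbian, Willshaw-type) weights. Provides the closed-form maximum capacity
    (N/S)^(S/D) for networks of N units storing patterns of sparsity S under a
    minimum pattern-differentiability constraint D, a deterministic grid-based
    construction of a fully saturated connectivity matrix that attains this
    maximum, a recursive backtracking enumerator of every storable pattern,
    random and cross-pattern-activation (CPA) guided sequential storage
    baselines, a brute-force exhaustive oracle for small networks, and a
    reorganization-cost analysis quantifying the bit-flip/pattern-deletion
    work needed to convert a suboptimal stored set into an optimal one.
    Includes plain-text pattern and matrix file formats and a command-line
    interface for reproducible capacity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
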