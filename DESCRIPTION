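Package: persistenergy
Title: Persistence Energy and Network Control Analysis of Brain States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Network-control-theory analysis of task-evoked brain activation
    states on a weighted structural connectome. Computes finite-horizon
    controllability Gramians and minimum control energy for linear dynamics,
    including the persistence energy required to maintain an activation state,
    per-region control input, and node-removal control impact. Provides
    degree-preserving structural rewiring nulls and spatial permutation nulls,
    linear mixed-effects inference for drug-by-group crossover designs,
    permutation tests of spatial alignment between control-input difference
    maps and receptor density maps, and a synthetic cohort generator that
    emulates a two-group pharmacological crossover study with injectable
    interaction effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    nlme,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
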