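Package: molanneal
Title: Adaptive Simulated Annealing for Multi-Constraint Molecular Graph Editing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A simulated-annealing framework for target-aware molecular
    generation by iterative graph editing. Molecules are edited with a
    complete four-operator set (insertion, replacement, deletion,
    cyclization) under a gated multi-property objective combining a
    docking-style affinity term, synthetic accessibility, drug-likeness,
    and a Morgan-similarity constraint to the starting fragment. Editing
    positions are proposed by a history-guided message-passing node
    regressor trained on atomic editing frequencies, and a reversible
    sampling strategy grants rejected candidates one secondary edit before
    final rejection. Includes a deterministic surrogate docking scorer so
    the full framework runs and tests without any external docking binary.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
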