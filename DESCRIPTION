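Package: egmcts
Title: Experience-Guided Monte Carlo Tree Search for Retrosynthetic Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multi-step retrosynthetic route planning by Monte Carlo tree
    search over AND-OR trees of molecules and reaction templates. Leaf
    evaluations come from an experience guidance network, a small value
    network trained on (molecule, template) scores harvested from the
    search's own successful and failed planning episodes. Includes a
    synthetic reaction-universe generator with known ground truth, the
    two-phase train/plan workflow, breadth-first route extraction,
    route-quality and matching-degree metrics, network-of-organic-chemistry
    construction for training-set selection, and a benchmark harness with
    greedy depth-first search and non-learning baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
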