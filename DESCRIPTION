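Package: segsuggest
Title: Effort-Aware Active Learning for Segmentation of 2D Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Active-learning framework for suggestive segmentation of stacks
    of 2D biomedical images (e.g. serial histological sections). Trains a
    pixel classifier from partial annotations and weak per-structure section
    bounds with a mixed cross-entropy loss, maintains boundary-length
    statistics to predict per-query annotation effort (crediting boundaries
    shared with already-traced neighbours), and iteratively suggests the
    (section, structure) pair that maximises predicted Dice gain per unit of
    tracing effort. Includes entropy, Monte Carlo dropout, random and
    slice-wise uniform baselines, ablated variants, a synthetic-stack
    generator with a simulated annotator, and Dice-versus-effort evaluation
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
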