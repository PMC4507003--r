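Package: searchkin
Title: Target-Search Kinetics of DNA-Binding Proteins from Single-Molecule
    Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the target search of DNA-binding proteins
    in mammalian nuclei, built around single-particle tracking and single-cell
    association data. Provides per-trajectory mean-square-displacement and
    instantaneous diffusion-coefficient analysis with Gaussian-mixture
    classification of mobility populations, running-window detection of
    transient DNA-binding events, survival-probability construction across
    continuous and time-lapse imaging protocols with photobleaching
    correction, exponential association-rate fitting at a target locus,
    closed-form facilitated-diffusion and clustered-target search-rate
    models, a two-state diffusion-binding trajectory simulator, and an
    exhaustive contiguous-match motif scanner for synthetic genomes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    graphics,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
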