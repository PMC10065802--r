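Package: timernet
Title: Logical Modelling of Timer Gene and Posterior Terminal Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a multi-valued logical model of how the Drosophila
    timer genes (caudal, Dichaete, odd-paired) interact with the posterior
    terminal system (tailless, huckebein, forkhead, wingless) to pattern
    the trunk, tail, hindgut, and posterior midgut of the blastoderm
    embryo. Provides a generic synchronous update engine with clamp-based
    mutant perturbations, the canonical seven-factor terminal network with
    an annotated 18-interaction table, a machine-checkable suite of
    qualitative genotype phenotypes, a sequential-segmentation network
    variant that reproduces segment-addition-zone-like wavefront dynamics
    on a growing cell row, and a synthetic expression-trace generator with
    boundary quantification utilities (windowing, per-trace normalisation,
    half-maximum boundary calling, mutant-versus-wild-type shifts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
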