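Package: stickermc
Title: Temporal-Logic Model Checking with DNA Sticker Automata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates DNA-computing-based model checking of basic CTL, ITL and
    PTL formulas with sticker automata. Formula automata and system runs are
    encoded as Watson-Crick complementary DNA strands, the annealing step is
    simulated in silico as an exact strand-tiling problem, and satisfaction is
    decided from the tiling readout. Ships the reference formula automata,
    codebooks and system models, a combinatorial group-experiment driver, and a
    Gillespie stochastic simulator for competitive hybridization kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
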