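Package: medeadyn
Title: Deterministic Dynamics of Medea and Peel Gene-Drive Elements
    Under Partial Selfing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genotype-frequency recursions, closed-form invasion thresholds
    and internal equilibria, and numerical separatrix scans for
    maternal-effect (Medea) and paternal-effect (peel) toxin-antidote
    gene-drive elements in partially selfing populations. Includes a
    sex-structured model of the androdioecious Caenorhabditis mating
    system (hermaphrodites self or outcross with males; males arise only
    from outcrossing) with a cost-of-males parameter, a cross-by-cross
    mating-table oracle for every recursion, fate classification and
    invasion-threshold grid scans, ternary phase-portrait coordinates,
    seeded fixture generation, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
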