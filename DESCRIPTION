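Package: pigsurv
Title: Simulation and Single-Step Genomic Prediction of Binary Survival in Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of pig populations with direct and
    maternal genetic control of a binary survival trait, and single-step
    genomic evaluation of that trait.  Simulates linkage disequilibrium over
    historical generations, litter-structured recent pedigrees, liability
    threshold phenotypes, and four genotyping strategies (all animals, a
    random 80 percent, only survivors, or none).  Fits maternal-effects
    animal models with identity, logit, or probit links through Henderson's
    mixed-model equations using pedigree (A), genomic (G), or combined (H)
    relationship matrices, estimates variance components by average-
    information REML, and scores genomic predictions by accuracy against
    true breeding values, dispersion-bias regression slopes, and realized
    selection differentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
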