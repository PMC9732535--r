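Package: rbdrive
Title: Transmission Ratio Distortion Tests for Robertsonian Chromosome
    Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of the number of Robertsonian (Rb)
    metacentric chromosomes inherited by offspring of multiple-Rb
    heterozygous parents. Implements the Mendelian binomial segregation
    null model and its Poisson-binomial generalization to per-trivalent
    drive, chi-square and Monte-Carlo goodness-of-fit tests for meiotic
    drive, transmission-proportion estimation with Wilson intervals,
    pericentromeric-length normalization (CL/TL x 100) and exceedance
    tests, and a simulator of trivalent segregation with drive and
    viability distortion for validating every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
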