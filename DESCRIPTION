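Package: sparsemet
Title: Genomic Prediction for Sparse Testing in Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating sparse multi-environment
    breeding trials with genomic prediction. Simulates marker and plot-level
    trial data with genotype-by-environment interaction, adjusts phenotypes
    to per-environment BLUEs under an incomplete-block mixed model, builds
    the VanRaden method-1 genomic relationship matrix, allocates genotypes
    to environments under non-overlapping/overlapping (NO/O) designs, fits
    environment + line (E+L), E+L+G, and reaction-norm E+L+G+GE Gaussian
    random-effects models with an eigendecomposition-accelerated Gibbs
    sampler, and summarises predictive ability and variance partitions over
    repetition-by-design cross-validation grids.
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
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
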