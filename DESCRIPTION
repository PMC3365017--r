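Package: gradecode
Title: Gradient Encoding Analysis of Polysome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide translational profiling by Gradient
    Encoding, in which mRNA from successive sucrose-gradient fractions is
    labeled with increasing Cy5:Cy3 proportions so that a single two-color
    microarray ratio reports each transcript's average position in the
    gradient. Provides gradient geometry and A260 peak calibration (elution
    time to average ribosome number), dye-ratio decoding with spike-in
    (doping control) regression, an explicit per-fraction qRT-PCR encoding
    oracle, a SAM-style permutation statistic with false discovery rate
    estimation for treated/untreated comparisons, pulsed-SILAC peptide to
    protein ratio aggregation, integration of translation, mRNA abundance
    and protein production changes, and a seeded synthetic-experiment
    generator with known ground truth for end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
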