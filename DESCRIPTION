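Package: cptradeoff
Title: Plant-Microbe Carbon-Pool Trade-Off Analysis for Grassland Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes aboveground, root and total plant community carbon
    pools and layered soil microbial biomass carbon pools from plot-level
    grassland measurements, and quantifies the trade-off between the total
    plant carbon pool and the microbial biomass carbon pool with a
    standardized-benefit root-mean-square-deviation index and a propensity
    classification relative to the 1:1 line. Includes per-grassland one-way
    ANOVA with Tukey HSD multiple comparisons and compact letter displays,
    a synthetic-data generator emulating a factorial grazing-by-litter
    field design with known ground truth, and an end-to-end pipeline that
    emits deterministic result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    car,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    multcomp,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
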