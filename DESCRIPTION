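Package: cecscreen
Title: Basin-Wide Screening of Contaminants of Emerging Concern in Water
    and Sediment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for multi-site screening surveys of
    contaminants of emerging concern (CECs) in surface water and bottom
    sediment. Takes raw left-censored concentration records through
    censored recoding, per-chemical detection-frequency summaries,
    ubiquity filtering, per-site maxima, and chemical-class totals;
    computes additive estradiol-equivalent (EEQ) estrogenicity scores;
    screens concentrations against chronic/acute water-quality benchmarks
    and tiered TEC/MEC/PEC sediment-quality guidelines; and performs
    two-way (chemicals by sites) agglomerative clustering of
    rank-transformed site maxima with deterministic tie-breaking and
    Newick export. Includes a seeded synthetic-data generator that
    emulates a multi-river monitoring network with land-use archetypes,
    lognormal concentrations, octanol-water partitioning, and censored
    reporting, so the whole pipeline runs end to end with no downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    withr
Config/testthat/edition: 3
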