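Package: gistcea
Title: Markov Cohort Cost-Effectiveness Model for Genotype-Directed
    Imatinib Dosing in Metastatic GIST
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic Markov cohort model comparing targeted gene
    testing (TGT) with KIT-exon-directed first-line imatinib dosing against
    empirical imatinib therapy for metastatic gastrointestinal stromal
    tumor (GIST). Converts progression-free and overall survival curves
    into per-cycle transition probabilities, accrues discounted costs and
    quality-adjusted life years over a 10-year horizon, and computes
    incremental cost-effectiveness ratios and net monetary benefit.
    Includes a seeded synthetic trial-curve generator, one-way and
    threshold sensitivity analyses, horizon and market-share scenario
    sweeps, and a probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
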