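Package: cnentropy
Title: DNA Copy Number Entropy Analysis for Array-CGH Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies inter-tumor genomic heterogeneity from array
    comparative genomic hybridization (aCGH) copy number profiles.
    Provides preprocessing of two-channel intensity tables into
    normalized, cellularity-corrected log2-ratio matrices, a
    permutation-based recursive binary segmentation of per-chromosome
    profiles, nearest-neighbour (Kozachenko-Leonenko) estimation of DNA
    copy number entropy with per-sample contributions, permutation tests
    of entropy differences between treatment groups (genome-wide and per
    chromosome with Benjamini-Hochberg correction), PCA-based dispersion
    summaries, and association of entropy with survival (Cox proportional
    hazards, Kaplan-Meier / log-rank) and clinical covariates. A seeded
    synthetic aCGH cohort generator with controllable aberration
    architecture, cellularity mixing and survival structure provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
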