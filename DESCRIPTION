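Package: meomics
Title: Growth-Coupled Metabolism-and-Expression Models with Paired
    RNA-Seq/Ribo-Seq Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and solving toy genome-scale models of
    metabolism and gene expression (ME-models) in which stoichiometric
    coefficients depend affinely on the growth rate. Maximum growth is
    found by bisection over linear-programming feasibility, with flux
    variability analysis, translation-knockout gene essentiality and
    substrate uptake scans that expose proteome limitation and overflow
    metabolism. A companion omics toolkit normalizes paired RNA-Seq and
    Ribo-Seq counts to CPM, computes translational efficiency, classifies
    pathway-level translational prioritization with one-tailed
    Mann-Whitney U tests on cross-dataset ranks, and benchmarks
    subsystem-aggregated model fluxes against omics signal by linear
    regression and Pearson correlation. Includes seeded generators for
    paired toy ME/M models and negative-binomial count data with planted
    pathway-level translational-efficiency effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    quadprog,
    boot,
    Matrix,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
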