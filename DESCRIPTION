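Package: introscan
Title: Introgression Mapping and Pool-Seq Outlier Scans for Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping adaptive introgression in replicated
    selection-and-backcross experiments genotyped by pooled sequencing.
    Provides a forward-in-time non-Wright-Fisher simulator of a
    16-generation backcross design with a two-step binomial pool-seq noise
    model and closed-form expected trajectories; pool-seq summary statistics
    (effective coverage, pairwise FST, global and sliding-window PCA,
    parent-similarity distance ratios); outlier scans calibrated against a
    simulated neutral drift envelope (top-quantile flagging, per-window
    binomial enrichment, synthetic-pool Fisher's exact tests with
    multiplicity control); clinality and seasonality tests for wild samples
    (lagged environmental summaries, binomial GLMs with effective-coverage
    weights, likelihood-ratio and permutation tests); two-locus phenotype
    statistics for inbred line panels (epistasis ANOVA, exact binomial
    intervals, negative-binomial interaction tests for expression); and
    synthetic-data generators so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    car
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
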