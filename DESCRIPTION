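Package: clinekit
Title: Genomic Cline Outlier Detection, Visualization, and Input/Output
    Tooling for Hybrid Zone Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for Bayesian genomic cline analyses of hybrid zones.
    Converts and filters SNP datasets (VCF, PHYLIP) into the custom input
    formats used by the 'bgc' and 'Introgress' genomic cline programs,
    aggregates 'bgc' MCMC posterior output across independent replicates
    with burn-in and thinning, classifies alpha/beta cline-parameter
    outlier loci by credible-interval and prior-quantile rules with sign
    tracking, computes and plots per-locus ancestry-probability (phi)
    clines against hybrid index, summarizes alpha-beta outlier space with
    density contours and polygon hulls, lifts SNP scaffold coordinates to
    chromosomes for annotated ideogram heatmaps, and regresses hybrid
    indices and per-locus clines on environmental covariates. A
    simulation module generates all supported input formats with known
    truth for validation, and a command-line entry point wires the
    modules into reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    ggplot2,
    grDevices,
    IRanges,
    jsonlite,
    MASS,
    patchwork,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
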