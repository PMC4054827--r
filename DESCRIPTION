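Package: twindrift
Title: Longitudinal Twin Methylation Analysis: Drift, Convergence and
    Age-Associated Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal DNA-methylation studies of
    twin pairs profiled on Infinium 450K-style arrays at two ages. Provides a
    synthetic twin-methylome generator with known ground truth (shared
    genetic, shared environmental and non-shared stochastic variance
    components on the log2-odds scale, planted age effects and multi-probe
    regions, pair-specific drift/convergence factors, technical replicates,
    detection failures and Infinium I/II design bias); probe- and
    sample-level quality control with beta/M transforms, within-array
    design-bias adjustment and between-array quantile normalization;
    empirical-Bayes moderated paired testing of age-associated
    differentially methylated probes with FDR and effect-size calling;
    bump-hunting detection of differentially methylated regions; genomic
    annotation enrichment with hypergeometric tests; within-pair discordance,
    delta-discordance and Euclidean-distance drift/converge/stable
    classification; and sample-relationship clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
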