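Package: prscreen
Title: Percentile-Ranking Analysis of Pooled In Vivo CRISPR Activation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification, normalization and percentile-ranking hit calling
    for pooled in vivo CRISPR activation screens read out through a severe
    clonal bottleneck, such as spontaneous-metastasis lung-colonization
    screens. Reads are matched exactly against a guide library, counts are
    filtered on the baseline ("0-hour") replicates, total-normalized against
    the grand mean sample depth, and guides are ranked by the number of
    animals in which they fall within the top abundance percentile of that
    animal's lung (n_NEP), with a z-score tie-break. A synthetic screen
    simulator (lognormal plasmid representation, multinomial injection,
    bottlenecked metastatic seeding with driver selection, lognormal clone
    outgrowth) provides ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
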