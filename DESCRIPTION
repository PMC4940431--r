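Package: panelcnv
Title: Germline Copy-Number Variant Inference from Targeted Panel Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers and visualizes germline copy-number variants (CNVs) from
    depth-of-coverage summaries of targeted hybrid-capture sequencing panels.
    Per-interval coverage is converted to fractional coverage, normalized
    against the batch median to log2 ratios, and corrected on the X chromosome
    for the sex composition of the batch via exact two-medoid clustering.
    Samples with over-dispersed log2 ratio distributions are removed by an
    iterative boxplot-whisker quality-control loop, candidate gains and losses
    are called under a dual fixed-threshold/whisker rule, recurrent cohort
    artifacts and extreme-GC calls are flagged, and review-grade static plots
    are produced. Includes a synthetic batch simulator with ground truth and a
    droplet digital PCR confirmation calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
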