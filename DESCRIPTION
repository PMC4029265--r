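Package: cimpanel
Title: Mining and Validating Prognostic DNA Methylation Marker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Clusters cancer patients into CpG-island-methylator phenotypes
    (CIMP) from genome-scale DNA methylation beta values, extracts epigenetic
    marker panels by methylation-expression concordance (hypermethylated and
    down-regulated, or hypomethylated and up-regulated, between phenotypes),
    and validates panels with Kaplan-Meier / log-rank / Cox survival
    comparisons, bootstrap cluster-stability analysis, and a random-gene
    permutation null. Includes a synthetic cohort generator with planted
    phenotype structure so every stage is testable without external data,
    and a command-line interface over the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust
Config/testthat/edition: 3
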