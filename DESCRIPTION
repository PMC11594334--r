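Package: spongenet
Title: Inference of circRNA-Mediated Competing Endogenous RNA Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds circRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    networks from back-spliced-junction (BSJ) count matrices. Provides
    junction-read confidence filtering, TMM-normalised negative-binomial
    differential expression, one-sided Pearson co-expression screening,
    miRNA seed-site scanning of circularised sequences, tripartite axis
    assembly with degree/MCC hub ranking and subnetwork extraction,
    Fisher and hypergeometric enrichment statistics, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
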