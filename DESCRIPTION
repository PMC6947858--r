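Package: vpchic
Title: Variant and Promoter Capture Hi-C Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-capture analysis of dual Variant Capture (VC) and Promoter
    Capture (PC) Hi-C experiments targeting GWAS risk signals. Provides a
    restriction-fragment data model with an in silico HindIII digest, capture
    bait design with sequence quality rules, thresholding and combination of
    CHiCAGO-style interaction scores with Peaky-style marginal posterior
    probabilities of contact (MPPC), distance- and count-matched permutation
    backgrounds for feature enrichment of interacting regions, a
    promoter-randomization permutation test for eQTL-loop co-occurrence,
    sequential fine-mapping of credible causal variants (CCVs), rule-based
    candidate target gene identification, and a seeded synthetic-data
    generator with ground-truth manifests for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
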