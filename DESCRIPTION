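Package: somaclock
Title: Somatic Epimutation Clocks in Long-Lived Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the accumulation of spontaneous DNA
    methylation changes (epimutations) within individual trees. The
    package calls per-cytosine and per-window methylation states from
    whole-genome bisulfite sequencing counts, computes pairwise
    methylation divergence and effect sizes, dates intra-organismal
    pedigrees from branch ages and ring-width series, estimates neutral
    per-year methylation gain and loss rates by nonlinear least squares,
    classifies gene-body-methylated genes, and ships a coupled simulator
    in which epimutation accrual scales with the cell-division rate so
    the mitotic-rate hypothesis can be exercised in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
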