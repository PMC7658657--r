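Package: slscreen
Title: Pan-Cancer Screening of Synthetic-Lethal Gene Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pan-cancer screening pipeline for candidate
    synthetic-lethal (SL) gene pairs. Builds a unified pair catalog from
    yeast genetic-interaction scores transferred through ortholog maps and
    from curated human SL databases; screens pairs by recurrent mutation
    (per-cancer mutation frequency across cohorts) and by recurrent
    expression dysregulation (a self-contained median-of-ratios plus
    Welch-test differential-expression engine); combines the two levels
    into mutated-gene/up-regulated-partner candidates; evaluates prognostic
    value with Kaplan-Meier log-rank grouping (MM/MW/WW, AA/AN/NN) against
    a randomization empirical null; associates pair mutation status with
    drug response; collapses isomiR tables to dominant sequences and
    assembles miRNA-mRNA regulatory networks. A synthetic-data generator
    with planted ground truth emulates every input so the full cascade is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
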