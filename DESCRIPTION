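Package: adenodrive
Title: Copy-Number Risk Stratification and Proteogenomic Driver Nomination
    for Colorectal Adenomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies colorectal adenomas into high- and low-risk classes
    from arm-level somatic copy-number profiles (seven cancer-associated
    events: gains of 8q, 13q, 20q and losses of 8p, 15q, 17p, 18q), quantifies
    differential RNA and protein expression between risk groups with an
    empirical-Bayes moderated t-test, performs preranked and single-sample
    gene set enrichment analysis including ESTIMATE-style stromal and immune
    scoring, and nominates candidate progression drivers by DNA copy-number
    driven gene-dosage effects concordant across DNA, RNA and protein layers.
    Ships a matched multi-omic cohort simulator with known ground truth so
    every stage is testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    withr
Config/testthat/edition: 3
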