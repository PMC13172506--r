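Package: poolwes
Title: Trio Pooled Whole-Exome Sequencing: Design, Simulation and
    Inheritance-Aware Variant Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a sequential diagnostic workflow in which parental
    DNA is sequenced in two pools (one maternal, one paternal) at elevated
    depth and used only to test presence or absence of each proband variant.
    Provides closed-form pool design mathematics (required depth, expected
    allelic balance, per-trio cost model), a synthetic-data generator for
    pooled read counts under controlled inheritance scenarios, a
    variant-allele-fraction based classifier of inheritance (de novo,
    maternal, paternal, biparental) with compound-heterozygote phasing, a
    mode-of-inheritance aware SNV prioritization cascade, a solo-exome CNV
    filtering cascade, and the validation statistics (sensitivity, allelic
    balance, diagnostic yield) used to qualify the pooling strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
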