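Package: vcfsift
Title: Sequential Variant Prioritization for Annotated VCF Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interactive-style variant prioritization for VCF 4.x files from any
    DNA sequencing experiment. Discovers every annotation field present in a
    file (core columns, INFO keys, FORMAT keys and VEP CSQ sub-fields), builds
    one compact on-disk index per user-selected field, and narrows large
    variant sets through five sequentially applied filter types: annotation
    cut-offs and keyword searches, genotype-class queries for family and
    tumour/normal designs, genomic-region queries, variant-type (SNP, InDel,
    MNP) extraction and gene-list queries. Every applied filter is recorded in
    a replayable history and results export as spreadsheet-compatible
    tab-separated text. Includes a deterministic synthetic-VCF generator for
    testing and demonstration, and a command-line interface for use in
    automated pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
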