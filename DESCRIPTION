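Package: xeniaseq
Title: Pollen-Parent (Xenia) Effects on Seed Rutin and Allele-Specific
    Expression in F1 Buckwheat Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Partitions maternal and pollen-parent (xenia) contributions to
    seed rutin content from per-seed measurements of parent lines and F1
    crosses (mid-parent values, maternal-effect mixture weights, Fisher's
    LSD significance), and quantifies pollen-parent allele expression in
    maturing F1 seeds from per-position nucleotide-count pileups by
    comparing a self-type cross against an outcross to a homozygous
    reference line (SNP pattern classification, pollen-allele ratios,
    per-locus and pathway-level summaries). Includes synthetic generators
    for both data types with known ground truth, and bundled reference
    tables from the motivating buckwheat crossing study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
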