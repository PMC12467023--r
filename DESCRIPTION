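Package: sbgturnover
Title: Turnover of Sex-Biased Gene Expression Across Insect Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative analysis of sex-biased gene (SBG) expression across
    insect species. Calls per-gene bias directions from sexed FPKM tables,
    aggregates them to order-level consensus, classifies single-copy
    orthologous gene families as consistently or non-consistently biased,
    attributes expression reversals ("turnover") to species, and screens
    gene trees for lineage-specific branch-length acceleration using
    Jukes-Cantor distances, neighbor joining and Robinson-Foulds
    comparison. Includes a ground-truth-labeled synthetic data generator
    (binary bias states evolving on a species tree, lognormal FPKM,
    Jukes-Cantor alignments) so every stage is testable without database
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
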