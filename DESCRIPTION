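Package: mucometa
Title: Functional and Taxonomic Analysis of Mucus-Associated Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of annotated shotgun-metagenome assemblies
    from rectal (mucus-associated) swabs. Builds a Metagenome Function
    Abundance (MFA) table of KEGG ortholog (KO) read counts from per-contig
    gene annotations, normalizes and transforms it, and links molecular
    functions to clinical characteristics: unsupervised hierarchical
    clustering, tumor-size group comparison by unadjusted Fisher and
    Mann-Whitney tests, a pathway enrichment score over differential KOs,
    CAZy family summaries, a two-normal-curve density decomposition that
    quantifies two co-existing microbial communities per metagenome,
    pathway activity scores with recurrence-free-survival association, and
    contig length-by-depth taxon quantification including
    pathway-representative taxonomy. Includes a synthetic cohort generator
    with the statistical structure the analysis assumes, for testing and
    power exploration.
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
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
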