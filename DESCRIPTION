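Package: pathmeta
Title: Integrative Pathway Meta-Analysis of GWAS and Regional Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for convergent pathway analysis of
    genome-wide association (GWAS) summary statistics and staged brain gene
    expression. SNPs are mapped to protein-coding genes with a symmetric
    base-pair window and a nearest-gene fallback; differential expression is
    computed within each subject between anatomically adjacent Braak regions
    and adjusted by the average control profile; each gene list is tested for
    pathway over-representation with the hypergeometric distribution; and the
    two pathway p-values are combined per pathway by Fisher's combined
    probability test with Bonferroni correction of the combined p-values.
    Includes a synthetic-data generator that plants a known pathway signal in
    both data types so the whole pipeline can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
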