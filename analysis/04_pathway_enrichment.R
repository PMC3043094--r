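#!/usr/bin/env Rscript
# Hypergeometric over-representation analysis of both gene lists: the GWAS
# query against the GWAS-reachable reference, and the merged differential
# list against the expression panel's gene universe.

suppressPackageStartupMessages(library(pathmeta))

cfg <- read_pipeline_config("results/sim/config.yaml")
pathways <- read_gmt("results/sim/pathways.gmt")
panel_genes <- read_gene_table("results/sim/annotation.tsv")$gene_id

gwas_query <- readLines("results/gwas_query_genes.txt")
gwas_ref <- readLines("results/gwas_reference_genes.txt")
expr_query <- readLines("results/expr_merged_genes.txt")

gwas_enr <- test_pathways(gwas_query, gwas_ref, pathways)
expr_enr <- test_pathways(expr_query, panel_genes, pathways)
write_enrichment(gwas_enr, "results/gwas_enrichment.tsv")
write_enrichment(expr_enr, "results/expr_enrichment.tsv")

gwas_sig <- significant_pathways(gwas_enr, cfg$pathway_alpha)
expr_sig <- significant_pathways(expr_enr, cfg$pathway_alpha)
writeLines(gwas_sig, "results/gwas_significant_pathways.txt")
writeLines(expr_sig, "results/expr_significant_pathways.txt")

report <- function(label, enr, sig) {
  best <- enr[which.min(enr$p_value), ]
  cat(sprintf("%s: %d/%d pathways testable, %d significant (p <= %g); top %s (k=%d/%d, p=%.3g)\n",
              label, sum(enr$tested), nrow(enr), length(sig),
              cfg$pathway_alpha, best$pathway_id, best$k, best$K,
              best$p_value))
}
report("GWAS study", gwas_enr, gwas_sig)
report("Expression study", expr_enr, expr_sig)
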