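#!/usr/bin/env Rscript
# Map SNPs to protein-coding genes with the +/-20 kbp window (nearest-gene
# fallback in gene deserts) and build the GWAS query and reference gene
# lists: the query from the top 5,000 SNPs with p < 0.01, the reference from
# every SNP in the study.

suppressPackageStartupMessages(library(pathmeta))

cfg <- read_pipeline_config("results/sim/config.yaml")
snps <- read_snp_table("results/sim/snps.tsv")
genes <- read_gene_table("results/sim/annotation.tsv")

top <- select_top_snps(snps, cfg$top_snp_count, cfg$snp_p_threshold)
assignments <- map_snps_to_genes(top, protein_coding(genes), cfg$window_bp)
write_snp_assignments(assignments, "results/top_snp_assignments.tsv")

query <- build_gene_list(top, genes, cfg$window_bp)
reference <- build_gene_list(snps, genes, cfg$window_bp)
write_gene_list(query, "results/gwas_query_genes.txt")
write_gene_list(reference, "results/gwas_reference_genes.txt")

cat(sprintf("Top SNPs passing p < %g: %d (cap %d)\n", cfg$snp_p_threshold,
            nrow(top), cfg$top_snp_count))
cat(sprintf("Assignment rules among top SNPs: %s\n",
            paste(sprintf("%s=%d", names(table(assignments$rule)),
                          table(assignments$rule)), collapse = ", ")))
cat(sprintf("GWAS query: %d unique genes; reference: %d genes\n",
            length(query), length(reference)))
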