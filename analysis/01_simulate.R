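#!/usr/bin/env Rscript
# Generate the synthetic study the rest of the workflow analyses: a genome
# annotation, a pathway catalogue with one planted pathway (PW001), GWAS
# summary statistics enriched for small p-values near planted genes, and a
# 5-region Braak-staged expression panel in which planted genes drift upward
# across stages in cases only. All downstream scripts read the files written
# here.

suppressPackageStartupMessages(library(pathmeta))

spec <- simulation_spec(rng_seed = 1L)
study <- gen_study(spec)
paths <- write_study(study, "results/sim")
write_pipeline_config(pipeline_config(rng_seed = spec$rng_seed),
                      "results/sim/config.yaml")

cat("Synthetic study written to results/sim/:\n")
cat(sprintf("  %d genes on %d chromosomes (%s)\n", nrow(study$annotation),
            spec$n_chrom, paths[["annotation"]]))
cat(sprintf("  %d pathways, planted: %s (%d genes)\n",
            length(study$pathways),
            paste(spec$planted_pathways, collapse = ", "),
            spec$planted_pathway_size))
cat(sprintf("  %d SNPs, %.1f%% with p < 0.01 (null expectation 1%%)\n",
            nrow(study$snps), 100 * mean(study$snps$p_value < 0.01)))
cat(sprintf("  expression panel: %d cases + %d controls x %d regions\n",
            spec$n_cases, spec$n_controls, length(spec$regions)))
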