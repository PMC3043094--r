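test_that("every generator is deterministic under a fixed seed", {
  spec <- small_spec(seed = 7)
  s1 <- gen_study(spec)
  s2 <- gen_study(spec)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$pathways, s2$pathways)
  expect_identical(s1$snps, s2$snps)
  expect_identical(s1$panel$values, s2$panel$values)
})

test_that("generators use independent streams: n_snps never perturbs the panel", {
  spec_a <- small_spec(seed = 3)
  spec_b <- small_spec(seed = 3, n_snps = 500L)
  ann <- gen_annotation(spec_a)
  pw <- gen_pathways(spec_a, ann)
  expect_identical(gen_expression(spec_a, ann, pw)$values,
                   gen_expression(spec_b, ann, pw)$values)
  expect_false(identical(gen_gwas(spec_a, ann, pw),
                         gen_gwas(spec_b, ann, pw)))
})

test_that("annotation lays out non-overlapping genes with the requested length", {
  spec <- simulation_spec(rng_seed = 11)  # 2000 genes, mean length 10 kbp
  ann <- gen_annotation(spec)
  expect_equal(nrow(ann), spec$n_genes)
  expect_true(all(ann$start <= ann$end))
  for (chrom in unique(ann$chrom)) {
    g <- ann[ann$chrom == chrom, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # law of large numbers: empirical mean length within 3 SE of the target
  # (exponential sd = mean)
  lens <- ann$end - ann$start + 1
  se <- spec$mean_gene_length_bp / sqrt(spec$n_genes)
  expect_lt(abs(mean(lens) - spec$mean_gene_length_bp), 3 * se)
})

test_that("pathway collection has requested count and sizes", {
  spec205 <- small_spec(seed = 5, n_pathways = 205L)
  ann <- gen_annotation(spec205)
  expect_length(gen_pathways(spec205, ann), 205)

  fixed <- small_spec(seed = 5, pathway_size_range = c(10L, 10L),
                      planted_pathway_size = 10L)
  sizes <- lengths(gen_pathways(fixed, gen_annotation(fixed))$sets)
  expect_true(all(sizes == 10))

  planted <- small_spec(seed = 5)
  pw <- gen_pathways(planted, gen_annotation(planted))
  expect_length(pw$sets$PW001, planted$planted_pathway_size)
  other <- lengths(pw$sets)[-1]
  expect_true(all(other >= planted$pathway_size_range[1] &
                    other <= planted$pathway_size_range[2]))
})

test_that("null GWAS p-values are uniform to binomial precision", {
  spec <- simulation_spec(rng_seed = 13, n_snps = 100000L,
                          gwas_effect_beta_a = 1)
  ann <- gen_annotation(spec)
  pw <- gen_pathways(spec, ann)
  snps <- gen_gwas(spec, ann, pw)
  frac <- mean(snps$p_value < 0.01)
  se <- sqrt(0.01 * 0.99 / spec$n_snps)
  expect_lt(abs(frac - 0.01), 3 * se)
})

test_that("planted-adjacent SNP p-values follow the Beta(a, 1) mean", {
  spec <- simulation_spec(rng_seed = 17, gwas_effect_beta_a = 0.2)
  ann <- gen_annotation(spec)
  pw <- gen_pathways(spec, ann)
  snps <- gen_gwas(spec, ann, pw)
  planted <- unique(unlist(pw$sets[spec$planted_pathways]))
  pg <- ann[ann$gene_id %in% planted, ]
  near <- vapply(seq_len(nrow(snps)), function(i) {
    g <- pg[pg$chrom == snps$chrom[i], ]
    any(g$start <= snps$pos[i] + spec$window_bp &
          g$end >= snps$pos[i] - spec$window_bp)
  }, logical(1))
  a <- spec$gwas_effect_beta_a
  beta_mean <- a / (a + 1)
  beta_sd <- sqrt(a / ((a + 1)^2 * (a + 2)))
  expect_gt(sum(near), 100)
  expect_lt(abs(mean(snps$p_value[near]) - beta_mean),
            3 * beta_sd / sqrt(sum(near)))
  # far SNPs stay uniform
  expect_lt(abs(mean(snps$p_value[!near]) - 0.5),
            3 * sqrt(1 / 12) / sqrt(sum(!near)))
})

test_that("planted genes carry the stated adjusted stage shift", {
  spec <- small_spec(seed = 19, noise_sd = 0.1)
  study <- gen_study(spec)
  planted <- study$pathways$sets$PW001
  ctrl <- control_average_deltas(study$panel)
  cases <- study$panel$subjects[study$panel$group == "case"]
  adj <- vapply(cases, function(s) {
    d <- adjust_case_deltas(adjacent_deltas(study$panel, s), ctrl$mean)
    mean(d[planted, ])
  }, numeric(1))
  # each adjacent transition adds stage_shift_per_transition (= 1) in cases
  expect_equal(mean(adj), spec$stage_shift_per_transition, tolerance = 0.05)
  # non-planted genes are centred at zero after adjustment
  nonplanted <- setdiff(study$annotation$gene_id, planted)
  adj0 <- mean(vapply(cases, function(s) {
    d <- adjust_case_deltas(adjacent_deltas(study$panel, s), ctrl$mean)
    mean(d[nonplanted, ])
  }, numeric(1)))
  expect_lt(abs(adj0), 0.05)
})

test_that("written study files round-trip through the package readers", {
  spec <- small_spec(seed = 23)
  study <- gen_study(spec)
  dir <- withr::local_tempdir()
  paths <- write_study(study, dir)
  expect_identical(read_gene_table(paths[["annotation"]]), study$annotation)
  expect_identical(read_gmt(paths[["pathways"]]), study$pathways)
  back_snps <- read_snp_table(paths[["snps"]])
  expect_identical(back_snps$snp_id, study$snps$snp_id)
  expect_equal(back_snps$p_value, study$snps$p_value, tolerance = 1e-12)
  panel <- read_expression_panel(paths[["cases"]], paths[["controls"]],
                                 spec$regions)
  expect_equal(panel$values, study$panel$values, tolerance = 1e-12)
})
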