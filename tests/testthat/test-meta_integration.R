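test_that("Fisher combination reproduces the worked examples", {
  none <- fisher_combine(1, 1)
  expect_equal(none$chi2_stat, 0)
  expect_equal(none$p_meta, 1)

  fc <- fisher_combine(0.01, 0.02)
  expect_equal(fc$chi2_stat, 17.0344, tolerance = 1e-4)
  expect_equal(fc$p_meta, 1.9034e-3, tolerance = 1e-4)

  half <- fisher_combine(0.05, 1)
  expect_equal(half$p_meta, 0.19979, tolerance = 1e-4)
})

test_that("chi-square (df 4) survival equals the closed form p1 p2 (1 - ln(p1 p2))", {
  set.seed(7)
  p1 <- runif(10000, 1e-12, 1)
  p2 <- runif(10000, 1e-12, 1)
  got <- fisher_combine(p1, p2)$p_meta
  closed <- p1 * p2 * (1 - log(p1 * p2))
  expect_lt(max(abs(got - closed) / closed), 1e-10)
  # symmetry
  expect_equal(got, fisher_combine(p2, p1)$p_meta)
})

test_that("combination is monotone in each input and dominated by partial evidence", {
  set.seed(8)
  p1 <- runif(200)
  p2 <- runif(200)
  base <- fisher_combine(p1, p2)$p_meta
  larger <- fisher_combine(pmin(p1 * 1.5, 1), p2)$p_meta
  expect_true(all(larger >= base - 1e-15))
  with_one <- fisher_combine(p1, rep(1, 200))$p_meta
  expect_true(all(base <= with_one + 1e-15))
})

test_that("invalid p-values fail; marginal rounding above 1 is clamped", {
  expect_error(fisher_combine(0, 0.5), "strictly positive")
  expect_error(fisher_combine(0.5, 1.01), "exceed 1")
  expect_warning(res <- fisher_combine(0.5, 1 + 1e-12), "clamped")
  expect_equal(res$p_meta, fisher_combine(0.5, 1)$p_meta)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni_correct(1e-3, 50), 0.05)
  expect_equal(bonferroni_correct(0.02, 100), 1.0)
  expect_equal(bonferroni_correct(1.39e-9, 201), 2.794e-7, tolerance = 1e-3)
})

test_that("the integer multiplier is recoverable from printed value pairs", {
  p <- c(2e-6, 3.5e-5, 1.2e-4, 4e-3)
  M <- 117
  printed <- signif(bonferroni_correct(p, M), 3)
  expect_equal(infer_bonferroni_multiplier(p, printed), M)
  capped <- bonferroni_correct(c(0.5, 0.9), M)
  expect_error(infer_bonferroni_multiplier(c(0.5, 0.9), capped), "capped")
})

test_that("meta-analysis combines only pathways testable in both studies", {
  gwas <- data.frame(
    pathway_id = c("P1", "P2", "P3", "P4"),
    name = paste("pathway", 1:4),
    p_value = c(0.01, 0.5, 1, 0.2),
    tested = c(TRUE, TRUE, TRUE, FALSE)
  )
  expr <- data.frame(
    pathway_id = c("P1", "P2", "P3", "P5"),
    name = paste("pathway", c(1, 2, 3, 5)),
    p_value = c(0.02, 0.5, 1, 0.001),
    tested = TRUE
  )
  meta <- meta_analysis(gwas, expr)
  expect_equal(attr(meta, "M"), 3)
  expect_equal(meta$pathway_id, c("P1", "P2", "P3"))
  expect_equal(meta$rank, 1:3)
  expect_equal(meta$p_meta,
               c(1.9034e-3, 0.5966, 1), tolerance = 1e-4)
  expect_equal(meta$p_corrected, pmin(1, 3 * meta$p_meta))
  # P4 untested in GWAS, P5 absent there: both excluded, listed uncombined
  expect_setequal(attr(meta, "uncombined"), "P5")

  # permuting input rows changes nothing
  meta2 <- meta_analysis(gwas[c(3, 1, 4, 2), ], expr[c(2, 4, 1, 3), ])
  expect_equal(meta2$p_meta, meta$p_meta)
  expect_equal(meta2$pathway_id, meta$pathway_id)
})

test_that("rank order is invariant to the Bonferroni universe and ties break by id", {
  res <- function(p) data.frame(pathway_id = sprintf("P%d", seq_along(p)),
                                name = "x", p_value = p, tested = TRUE)
  m_small <- meta_analysis(res(c(0.3, 0.01, 0.2)), res(c(0.3, 0.01, 0.2)))
  extra <- meta_analysis(res(c(0.3, 0.01, 0.2, 0.5, 0.6)),
                         res(c(0.3, 0.01, 0.2, 0.5, 0.6)))
  expect_equal(m_small$pathway_id[m_small$rank <= 3],
               extra$pathway_id[extra$rank <= 3])

  tied <- meta_analysis(res(c(0.2, 0.2)), res(c(0.2, 0.2)))
  expect_equal(tied$pathway_id, c("P1", "P2"))
})

test_that("overlap report counts shared significant pathways", {
  rep1 <- overlap_report(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(rep1$n_gwas_sig, 3)
  expect_equal(rep1$n_expr_sig, 3)
  expect_equal(rep1$n_common, 2)
  expect_equal(rep1$common_ids, c("b", "c"))
  expect_equal(overlap_report(c("a"), c("b"))$n_common, 0)
  same <- overlap_report(letters[1:12], letters[1:12])
  expect_equal(same$n_common, 12)
})

test_that("gene provenance labels members by query membership", {
  gsc <- gene_set_collection(list(P1 = c("g1", "g2", "g3", "g4")))
  prov <- pathway_gene_provenance("P1", gwas_query = c("g1", "g2"),
                                  expr_query = c("g2", "g3"), gsc)
  expect_equal(setNames(prov$label, prov$gene),
               c(g1 = "gwas_only", g2 = "both", g3 = "expr_only",
                 g4 = "neither"))
  expect_error(pathway_gene_provenance("missing", "g1", "g2", gsc),
               "unknown pathway")
})
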