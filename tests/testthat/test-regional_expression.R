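test_that("adjacent deltas subtract the earlier Braak stage from the later", {
  panel <- tiny_panel(genes = c("g1", "g2"),
                      regions = c("DMV", "LCER", "SNGRA"))
  panel$values["g1", "case01", "DMV"] <- 6.0
  panel$values["g1", "case01", "LCER"] <- 8.0
  d <- adjacent_deltas(panel, "case01")
  expect_equal(dim(d), c(2, 2))  # 3 regions -> 2 pairs
  expect_equal(d["g1", "LCER_vs_DMV"], 2.0)
  expect_equal(d["g2", "LCER_vs_DMV"], 0.0)
  expect_error(adjacent_deltas(panel, "nobody"), "unknown subject")

  five <- tiny_panel(regions = BRAAK_REGIONS)
  expect_equal(ncol(adjacent_deltas(five, "case01")), 4)  # four subtractions
})

test_that("control averages use the arithmetic mean and n-1 standard deviation", {
  panel <- tiny_panel(genes = "g1", n_cases = 1, n_controls = 4,
                      regions = c("DMV", "LCER"), fill = 0)
  deltas <- c(0.4, 0.6, 0.5, 0.5)
  for (i in 1:4) {
    panel$values["g1", paste0("ctrl0", i), "LCER"] <- deltas[i]
  }
  ctrl <- control_average_deltas(panel)
  expect_equal(ctrl$mean["g1", "LCER_vs_DMV"], 0.5)
  expect_equal(ctrl$n_controls, 4)

  two <- tiny_panel(genes = "g1", n_cases = 1, n_controls = 2,
                    regions = c("DMV", "LCER"), fill = 0)
  two$values["g1", "ctrl02", "LCER"] <- 1.0
  c2 <- control_average_deltas(two)
  expect_equal(c2$mean["g1", "LCER_vs_DMV"], 0.5)
  expect_equal(c2$sd["g1", "LCER_vs_DMV"], sqrt(0.5), tolerance = 1e-12)

  flat <- tiny_panel(genes = "g1", n_cases = 1, n_controls = 3,
                     regions = c("DMV", "LCER"))
  expect_equal(control_average_deltas(flat)$sd["g1", "LCER_vs_DMV"], 0)
})

test_that("case deltas are adjusted by subtracting the control mean", {
  mk <- function(x) matrix(x, 1, 1, dimnames = list("g1", "LCER_vs_DMV"))
  expect_equal(adjust_case_deltas(mk(2.0), mk(0.5)), mk(1.5))
  expect_equal(adjust_case_deltas(mk(0.5), mk(0.5)), mk(0.0))
  expect_equal(adjust_case_deltas(mk(-1.0), mk(-0.2)), mk(-0.8))
  wrong <- matrix(0.5, 1, 1, dimnames = list("other", "LCER_vs_DMV"))
  expect_error(adjust_case_deltas(mk(1), wrong), "different genes")
})

test_that("z-test, fold-change gate and BH stratum give the documented calls", {
  cfg <- pipeline_config()
  mk <- function(x, genes) matrix(x, length(genes), 1,
                                  dimnames = list(genes, "LCER_vs_DMV"))
  adjusted <- mk(c(1.5, 0, 0.5), c("gA", "gB", "gC"))
  sds <- mk(c(0.5, 0.5, 0.001), c("gA", "gB", "gC"))
  calls <- call_differential(adjusted, sds, 4, cfg)

  # z = 1.5 / (0.5 * sqrt(1.25)) = 2.6833, two-sided normal p = 0.00729
  rowA <- calls[calls$gene == "gA", ]
  expect_equal(rowA$p_value, 2 * pnorm(-1.5 / (0.5 * sqrt(1.25))))
  expect_equal(rowA$p_value, 0.00729, tolerance = 1e-3)

  rowB <- calls[calls$gene == "gB", ]
  expect_equal(rowB$p_value, 1)
  expect_equal(rowB$call, "none")

  # gC: minuscule p but adjusted 0.5 < log2(1.6) = 0.678: gate refuses
  rowC <- calls[calls$gene == "gC", ]
  expect_lt(rowC$q_value, 0.001)
  expect_equal(rowC$call, "none")
})

test_that("zero control spread makes a gene uncallable, never infinitely significant", {
  cfg <- pipeline_config()
  mk <- function(x) matrix(x, 2, 1,
                           dimnames = list(c("g1", "g2"), "LCER_vs_DMV"))
  expect_message(
    calls <- call_differential(mk(c(3.0, 0.1)), mk(c(0, 0.5)), 4, cfg),
    "zero control spread"
  )
  expect_equal(calls$p_value[calls$gene == "g1"], 1)
  expect_equal(calls$call[calls$gene == "g1"], "none")
})

test_that("Benjamini-Hochberg matches the hand-derived step-up values", {
  expect_equal(benjamini_hochberg(c(0.001, 0.01, 0.02, 0.04)),
               c(0.004, 0.02, 4 * 0.02 / 3, 0.04))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("gene lists collect calls across strata with set semantics", {
  tbl <- data.frame(
    gene = c("g1", "g1", "g2", "g3"),
    subject = c("case01", "case02", "case01", "case01"),
    pair = "LCER_vs_DMV",
    call = c("up", "down", "none", "up")
  )
  lists <- collect_gene_lists(tbl)
  expect_equal(lists$up, c("g1", "g3"))
  expect_equal(lists$down, "g1")
  expect_equal(lists$merged, c("g1", "g3"))  # g1 counted once

  empty <- collect_gene_lists(tbl[tbl$call == "none", ])
  expect_length(empty$merged, 0)
})

test_that("controls enter only through mean and sd: relabelling changes nothing", {
  spec <- small_spec(seed = 31)
  study <- gen_study(spec)
  tbl1 <- subtraction_table(study$panel, pipeline_config())

  panel2 <- study$panel
  ctrl_idx <- which(panel2$group == "control")
  perm <- rev(ctrl_idx)
  reorder <- c(which(panel2$group == "case"), perm)
  values <- panel2$values[, reorder, , drop = FALSE]
  dimnames(values)[[2]] <- panel2$subjects[c(which(panel2$group == "case"),
                                             ctrl_idx)]
  panel2 <- expression_panel(values, panel2$group)
  tbl2 <- subtraction_table(panel2, pipeline_config())
  expect_equal(tbl1$q_value, tbl2$q_value)
  expect_equal(tbl1$call, tbl2$call)
})

test_that("negating the panel swaps up and down calls exactly", {
  spec <- small_spec(seed = 37)
  study <- gen_study(spec)
  cfg <- pipeline_config()
  tbl_pos <- subtraction_table(study$panel, cfg)
  neg <- expression_panel(-study$panel$values, study$panel$group)
  tbl_neg <- subtraction_table(neg, cfg)
  lists_pos <- collect_gene_lists(tbl_pos)
  lists_neg <- collect_gene_lists(tbl_neg)
  expect_identical(lists_pos$up, lists_neg$down)
  expect_identical(lists_pos$down, lists_neg$up)
  expect_identical(lists_pos$merged, lists_neg$merged)
})

test_that("planted genes are recovered and strongly enriched in the merged list", {
  spec <- small_spec(seed = 41)
  study <- gen_study(spec)
  tbl <- subtraction_table(study$panel, pipeline_config())
  lists <- collect_gene_lists(tbl)
  planted <- study$pathways$sets$PW001
  nonplanted <- setdiff(study$annotation$gene_id, planted)
  frac_planted <- mean(planted %in% lists$merged)
  frac_other <- mean(nonplanted %in% lists$merged)
  expect_gte(frac_planted, 0.95)
  expect_gt(frac_planted, frac_other + 0.3)
})
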