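#' Fisher's combined probability test for two p-values
#'
#' Combines a GWAS pathway p-value and an expression pathway p-value by
#' adding `-2 ln p` for the two tests; the statistic follows a chi-square
#' distribution with 4 degrees of freedom (2 per independent test), whose
#' survival function gives the combined p-value. For two inputs this equals
#' the closed form `p1 p2 (1 - ln(p1 p2))`.
#'
#' Inputs must be strictly positive; values marginally above 1 (upstream
#' rounding) are clamped to 1 with a warning.
#'
#' @param p_gwas,p_expr p-values in `(0, 1]`; vectorized.
#' @return List with `chi2_stat` and `p_meta`.
#' @export
fisher_combine <- function(p_gwas, p_expr) {
  check <- function(p, label) {
    if (any(is.na(p)) || any(p <= 0)) {
      stop(label, " p-values must be strictly positive")
    }
    if (any(p > 1)) {
      if (any(p > 1 + 1e-8)) stop(label, " p-values exceed 1")
      warning(label, " p-value marginally above 1 clamped to 1")
      p <- pmin(p, 1)
    }
    p
  }
  p_gwas <- check(p_gwas, "GWAS")
  p_expr <- check(p_expr, "expression")
  chi2 <- -2 * (log(p_gwas) + log(p_expr))
  list(chi2_stat = chi2,
       p_meta = pchisq(chi2, df = 4, lower.tail = FALSE))
}

#' Bonferroni correction
#'
#' @param p_meta Combined p-value(s).
#' @param M Number of tests performed.
#' @return `min(1, M * p_meta)`.
#' @export
bonferroni_correct <- function(p_meta, M) {
  stopifnot(M >= 1, M == round(M))
  pmin(1, M * p_meta)
}

#' Infer an integer Bonferroni multiplier from reported value pairs
#'
#' Given reported combined p-values and their corrected counterparts, the
#' multiplier is the rounded median of the uncapped ratios
#' `corrected / combined`. Pairs whose corrected value hit the cap at 1 carry
#' no information and are dropped.
#'
#' @param p_meta Reported combined p-values.
#' @param p_corrected Reported corrected p-values.
#' @return The inferred integer multiplier.
#' @export
infer_bonferroni_multiplier <- function(p_meta, p_corrected) {
  stopifnot(length(p_meta) == length(p_corrected), length(p_meta) >= 1)
  keep <- p_corrected < 1
  if (!any(keep)) stop("all corrected values are capped at 1; multiplier unidentifiable")
  as.integer(round(median(p_corrected[keep] / p_meta[keep])))
}

#' Meta-analysis of GWAS and expression pathway results
#'
#' Combines, per pathway, the GWAS and expression over-representation
#' p-values by [fisher_combine()]. Only pathways testable in BOTH analyses
#' are combined; their count `M` is the Bonferroni universe for the
#' corrected p-values. Results are ranked ascending by combined p-value with
#' ties broken lexicographically by pathway id; pathways testable in only
#' one analysis are listed in the `uncombined` attribute.
#'
#' @param gwas_results,expr_results Data.frames from [test_pathways()].
#' @return Data.frame with columns `pathway_id`, `name`, `p_gwas`, `p_expr`,
#'   `chi2_stat`, `p_meta`, `p_corrected`, `rank`; attributes `M` and
#'   `uncombined`.
#' @export
meta_analysis <- function(gwas_results, expr_results) {
  g <- gwas_results[gwas_results$tested, , drop = FALSE]
  e <- expr_results[expr_results$tested, , drop = FALSE]
  shared <- intersect(g$pathway_id, e$pathway_id)
  if (length(shared) == 0) {
    stop("no pathway is testable in both analyses; nothing to combine")
  }
  g <- g[match(shared, g$pathway_id), ]
  e <- e[match(shared, e$pathway_id), ]
  comb <- fisher_combine(g$p_value, e$p_value)
  M <- length(shared)
  out <- data.frame(
    pathway_id = shared,
    name = g$name,
    p_gwas = g$p_value,
    p_expr = e$p_value,
    chi2_stat = comb$chi2_stat,
    p_meta = comb$p_meta,
    p_corrected = bonferroni_correct(comb$p_meta, M)
  )
  out <- out[order(out$p_meta, out$pathway_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "M") <- M
  attr(out, "uncombined") <- sort(setdiff(
    union(gwas_results$pathway_id[gwas_results$tested],
          expr_results$pathway_id[expr_results$tested]),
    shared))
  out
}

#' Overlap of significant pathway sets
#'
#' Summarizes the convergence of the two single-study analyses: how many
#' pathways each study calls over-represented and how many are shared.
#'
#' @param gwas_sig,expr_sig Character vectors of significant pathway ids.
#' @return List with `n_gwas_sig`, `n_expr_sig`, `n_common`, `common_ids`.
#' @export
overlap_report <- function(gwas_sig, expr_sig) {
  common <- sort(intersect(gwas_sig, expr_sig))
  list(n_gwas_sig = length(unique(gwas_sig)),
       n_expr_sig = length(unique(expr_sig)),
       n_common = length(common),
       common_ids = common)
}

#' Per-gene provenance within a pathway
#'
#' Labels each member of a pathway by which query gene list(s) it belongs
#' to, mirroring the two-colour pathway-diagram annotation: significant in
#' the GWAS study, in the expression study, in both, or in neither.
#'
#' @param pathway_id Pathway to annotate.
#' @param gwas_query,expr_query Character vectors of query gene ids.
#' @param pathways A `gene_set_collection`.
#' @return Data.frame with columns `gene` and `label`
#'   (`gwas_only`/`expr_only`/`both`/`neither`).
#' @export
pathway_gene_provenance <- function(pathway_id, gwas_query, expr_query,
                                    pathways) {
  stopifnot(inherits(pathways, "gene_set_collection"))
  members <- pathways$sets[[pathway_id]]
  if (is.null(members)) stop("unknown pathway: ", pathway_id)
  in_g <- members %in% gwas_query
  in_e <- members %in% expr_query
  label <- ifelse(in_g & in_e, "both",
                  ifelse(in_g, "gwas_only",
                         ifelse(in_e, "expr_only", "neither")))
  data.frame(gene = members, label = label)
}

#' Write the ranked meta-analysis table
#'
#' @param meta Data.frame from [meta_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta_table <- function(meta, path) {
  out <- meta
  num <- c("p_gwas", "p_expr", "chi2_stat", "p_meta", "p_corrected")
  for (col in num) out[[col]] <- format(out[[col]], digits = 8)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the overlap report as a small text block plus id list
#'
#' @param report List from [overlap_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(report, path) {
  lines <- c(
    sprintf("gwas_significant\t%d", report$n_gwas_sig),
    sprintf("expr_significant\t%d", report$n_expr_sig),
    sprintf("common\t%d", report$n_common),
    sprintf("common_ids\t%s", paste(report$common_ids, collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}
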