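#' Upper-tail hypergeometric probability
#'
#' Over-representation probability `P(X >= k)` for `X` hypergeometric with
#' reference universe size `N`, `K` pathway members in the reference and a
#' query of size `n`. Evaluated through the log-space hypergeometric CDF, so
#' it stays accurate deep in the tail.
#'
#' @param k Observed overlap between query and pathway.
#' @param N Reference universe size.
#' @param K Pathway members inside the reference.
#' @param n Query size.
#' @return `P(X >= k)`, in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, N, K, n) {
  stopifnot(
    length(k) == length(N) || length(k) == 1 || length(N) == 1,
    all(N >= 0), all(K >= 0), all(n >= 0), all(k >= 0),
    all(K <= N), all(n <= N)
  )
  if (any(k > pmin(K, n))) {
    stop("impossible overlap: k exceeds min(K, n)")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Test pathways for over-representation of a query gene list
#'
#' Classical hypergeometric comparison of a query gene list against a
#' reference gene list. Query genes absent from the reference are trimmed
#' with a message. Pathways with no members in the reference cannot be
#' tested and are reported with `tested = FALSE` and `p_value = NA`; an
#' empty query yields p = 1 for every testable pathway, with a warning.
#'
#' @param query Character vector of query gene ids.
#' @param reference Character vector, the gene universe.
#' @param pathways A `gene_set_collection`.
#' @return Data.frame with one row per pathway: `pathway_id`, `name`, `N`,
#'   `K`, `n`, `k`, `p_value`, `tested`.
#' @export
test_pathways <- function(query, reference, pathways) {
  stopifnot(inherits(pathways, "gene_set_collection"))
  reference <- unique(as.character(reference))
  if (length(reference) == 0) stop("reference gene list is empty")
  query <- unique(as.character(query))
  trimmed <- setdiff(query, reference)
  if (length(trimmed) > 0) {
    message(sprintf("test_pathways: trimmed %d query gene(s) absent from the reference",
                    length(trimmed)))
    query <- intersect(query, reference)
  }
  if (length(query) == 0) {
    warning("empty query gene list: every testable pathway gets p = 1")
  }
  ids <- names(pathways$sets)
  N <- length(reference)
  n <- length(query)
  K <- vapply(pathways$sets, function(m) sum(m %in% reference), integer(1))
  k <- vapply(pathways$sets, function(m) sum(m %in% query), integer(1))
  tested <- K >= 1
  p <- rep(NA_real_, length(ids))
  p[tested] <- hypergeom_upper_tail(k[tested], N, K[tested], n)
  data.frame(
    pathway_id = ids,
    name = unname(pathways$descriptions[ids]),
    N = N, K = unname(K), n = n, k = unname(k),
    p_value = p, tested = unname(tested),
    row.names = NULL
  )
}

#' Significant over-represented pathways
#'
#' @param results Data.frame from [test_pathways()].
#' @param alpha Significance level; the cut is inclusive (`p <= alpha`).
#' @return Sorted character vector of significant pathway ids.
#' @export
significant_pathways <- function(results, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  sort(results$pathway_id[results$tested & results$p_value <= alpha])
}

#' Write enrichment results
#'
#' @param results Data.frame from [test_pathways()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
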