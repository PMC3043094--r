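#' Per-subject deltas between adjacent Braak regions
#'
#' For a subject, computes for every gene and every consecutive region pair
#' the difference later-stage minus earlier-stage, e.g. the DMV value is
#' subtracted from the LCER value. Five regions yield four subtractions.
#'
#' @param panel An `expression_panel`.
#' @param subject Subject id present in the panel.
#' @return Numeric matrix genes x pairs; pair columns are named
#'   `"<later>_vs_<earlier>"`.
#' @export
adjacent_deltas <- function(panel, subject) {
  stopifnot(inherits(panel, "expression_panel"))
  if (!subject %in% panel$subjects) {
    stop("unknown subject: ", subject)
  }
  r <- panel$regions
  mat <- matrix(panel$values[, subject, ], nrow = length(panel$genes),
                dimnames = list(panel$genes, r))
  out <- mat[, -1, drop = FALSE] - mat[, -length(r), drop = FALSE]
  colnames(out) <- region_pairs(r)
  out
}

region_pairs <- function(regions) {
  paste0(regions[-1], "_vs_", regions[-length(regions)])
}

#' Average and spread of the control subtraction profiles
#'
#' Controls are treated as replicates: for every gene and adjacent-region
#' pair, the arithmetic mean and the sample standard deviation (n - 1
#' denominator) of the per-control deltas are computed. At least two controls
#' are required, otherwise the spread is undefined.
#'
#' @param panel An `expression_panel`.
#' @return List with matrices `mean` and `sd` (genes x pairs) and
#'   `n_controls`.
#' @export
control_average_deltas <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  controls <- panel$subjects[panel$group == "control"]
  if (length(controls) < 2) {
    stop("need at least 2 controls to estimate the control delta spread")
  }
  deltas <- lapply(controls, function(s) adjacent_deltas(panel, s))
  arr <- array(unlist(deltas, use.names = FALSE),  # genes x pairs x controls
               dim = c(dim(deltas[[1]]), length(deltas)),
               dimnames = c(dimnames(deltas[[1]]), list(controls)))
  n <- length(controls)
  m <- rowMeans(arr, dims = 2)
  centred <- arr - as.vector(m)  # recycles over the control dimension
  list(
    mean = m,
    sd = sqrt(rowSums(centred^2, dims = 2) / (n - 1)),
    n_controls = n
  )
}

#' Adjust case deltas by the control average
#'
#' Subtracts the average control subtraction profile from a case subject's
#' raw deltas, removing the shared region-to-region baseline differences
#' (the normal functional variation between brain regions).
#'
#' @param case_deltas Genes x pairs matrix from [adjacent_deltas()].
#' @param control_means Genes x pairs matrix (the `mean` element of
#'   [control_average_deltas()]).
#' @return Adjusted delta matrix, same shape.
#' @export
adjust_case_deltas <- function(case_deltas, control_means) {
  if (!identical(dimnames(case_deltas), dimnames(control_means))) {
    stop("case and control delta tables index different genes or pairs")
  }
  case_deltas - control_means
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Call differential expression for one case subject
#'
#' For each gene and adjacent-region pair the adjusted delta is referred to
#' the control-replicate delta distribution with a z statistic,
#' `z = adjusted / (sd * sqrt(1 + 1/n_controls))`, whose `sqrt(1 + 1/n_c)`
#' factor accounts for estimating the control mean from `n_c` replicates.
#' Two-sided normal p-values are converted to q-values by Benjamini-Hochberg
#' across all genes within each region pair (each subtraction is its own
#' stratum). A gene is called up when `q < q_threshold` and the adjusted
#' delta reaches `+log2(fold_change_threshold)`, down symmetrically, and
#' `none` otherwise. Genes with zero control spread in a pair are uncallable:
#' p is set to 1 and the count is reported in a message.
#'
#' @param adjusted Genes x pairs adjusted-delta matrix.
#' @param control_sd Genes x pairs control standard-deviation matrix.
#' @param n_controls Number of control replicates behind `control_sd`.
#' @param config A `pipeline_config`.
#' @return Long data.frame with columns `gene`, `pair`, `adjusted_delta`,
#'   `p_value`, `q_value`, `call`.
#' @export
call_differential <- function(adjusted, control_sd, n_controls, config) {
  stopifnot(inherits(config, "pipeline_config"), n_controls >= 2)
  if (!identical(dimnames(adjusted), dimnames(control_sd))) {
    stop("adjusted deltas and control sds index different genes or pairs")
  }
  lfc <- log2(config$fold_change_threshold)
  zero_sd <- control_sd == 0
  if (any(zero_sd)) {
    message(sprintf("call_differential: %d gene/pair cell(s) with zero control spread left uncalled",
                    sum(zero_sd)))
  }
  z <- adjusted / (control_sd * sqrt(1 + 1 / n_controls))
  p <- 2 * pnorm(-abs(z))
  p[zero_sd] <- 1
  q <- p
  for (j in seq_len(ncol(p))) q[, j] <- benjamini_hochberg(p[, j])
  call <- matrix("none", nrow(adjusted), ncol(adjusted))
  call[q < config$q_threshold & adjusted >= lfc & !zero_sd] <- "up"
  call[q < config$q_threshold & adjusted <= -lfc & !zero_sd] <- "down"
  data.frame(
    gene = rep(rownames(adjusted), times = ncol(adjusted)),
    pair = rep(colnames(adjusted), each = nrow(adjusted)),
    adjusted_delta = as.vector(adjusted),
    p_value = as.vector(p),
    q_value = as.vector(q),
    call = as.vector(call)
  )
}

#' Full subtraction analysis over all case subjects
#'
#' Runs the within-subject subtraction design end to end: raw adjacent
#' deltas per case, control-average adjustment, and differential calls per
#' (subject, pair) stratum.
#'
#' @param panel An `expression_panel`.
#' @param config A `pipeline_config`.
#' @return Long data.frame with columns `gene`, `subject`, `pair`,
#'   `raw_delta`, `adjusted_delta`, `p_value`, `q_value`, `call`.
#' @export
subtraction_table <- function(panel, config = pipeline_config()) {
  stopifnot(inherits(panel, "expression_panel"))
  ctrl <- control_average_deltas(panel)
  cases <- panel$subjects[panel$group == "case"]
  pieces <- lapply(cases, function(s) {
    raw <- adjacent_deltas(panel, s)
    adj <- adjust_case_deltas(raw, ctrl$mean)
    calls <- call_differential(adj, ctrl$sd, ctrl$n_controls, config)
    data.frame(gene = calls$gene, subject = s, pair = calls$pair,
               raw_delta = as.vector(raw),
               adjusted_delta = calls$adjusted_delta,
               p_value = calls$p_value, q_value = calls$q_value,
               call = calls$call)
  })
  do.call(rbind, pieces)
}

#' Collect up-, down- and merged differential gene lists
#'
#' A gene enters the up (down) list when it is called up (down) in at least
#' one (subject, pair) stratum; the merged list is the union of the two, each
#' gene counted once. A gene may be up in one stratum and down in another and
#' then belongs to all three lists.
#'
#' @param sub_table Long table from [subtraction_table()].
#' @return List of class `differential_gene_lists` with sorted character
#'   vectors `up`, `down`, `merged`.
#' @export
collect_gene_lists <- function(sub_table) {
  up <- sort(unique(sub_table$gene[sub_table$call == "up"]))
  down <- sort(unique(sub_table$gene[sub_table$call == "down"]))
  structure(list(up = up, down = down, merged = sort(union(up, down))),
            class = "differential_gene_lists")
}

#' Write the subtraction table
#'
#' @param sub_table Long table from [subtraction_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subtraction_table <- function(sub_table, path) {
  write.table(sub_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
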