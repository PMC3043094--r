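#' Map SNPs to genes by window with nearest-gene fallback
#'
#' Implements the two-step mapping rule. A gene is assigned to a SNP when its
#' `[start, end]` interval intersects the closed window
#' `[pos - window_bp, pos + window_bp]` (inclusive at exactly `window_bp`
#' distance). When no gene lies in the window, the nearest gene strictly left
#' of the SNP and the nearest strictly right of it on the same chromosome are
#' both assigned, irrespective of distance; one side may be absent near a
#' chromosome end. Fallback distance is `min(|pos - start|, |pos - end|)`
#' and exact ties on a side are broken toward the smaller `gene_id` for
#' determinism.
#'
#' SNPs on chromosomes with no annotated gene receive an empty assignment and
#' their count is reported in a warning.
#'
#' @param snps SNP association data.frame (`snp_id`, `chrom`, `pos`, ...).
#' @param genes Gene annotation, pre-filtered to protein-coding genes (see
#'   [protein_coding()]).
#' @param window_bp Window half-width in base pairs.
#' @return A data.frame with columns `snp_id`, `rule`
#'   (`"window"`/`"nearest_fallback"`) and list-column `genes` of assigned
#'   gene ids (sorted character vectors).
#' @export
map_snps_to_genes <- function(snps, genes, window_bp) {
  stopifnot(is.data.frame(snps), is.data.frame(genes), window_bp >= 0)
  n <- nrow(snps)
  assigned <- rep(list(character(0)), n)
  rule <- rep("window", n)
  if (n == 0) {
    return(data.frame(snp_id = character(), rule = character(),
                      genes = I(list())))
  }
  if (nrow(genes) > 0) {
    # chromosomes private to one side are legitimate (handled below), so the
    # seqlevel-mismatch warning findOverlaps raises for them is muffled
    hits <- withCallingHandlers(
      findOverlaps(
        GRanges(snps$chrom,
                IRanges(snps$pos - window_bp, snps$pos + window_bp)),
        GRanges(genes$chrom, IRanges(genes$start, genes$end))
      ),
      warning = function(w) {
        if (grepl("sequence levels in common", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    if (length(hits) > 0) {
      # findOverlaps yields each (snp, gene) pair once; pre-sorting by
      # (snp, gene_id) makes every per-SNP assignment a sorted unique set.
      qh <- queryHits(hits)
      gid <- genes$gene_id[subjectHits(hits)]
      o <- order(qh, gid)
      by_snp <- split(gid[o], qh[o])
      assigned[as.integer(names(by_snp))] <- unname(by_snp)
    }
  }
  no_window <- which(lengths(assigned) == 0)
  rule[no_window] <- "nearest_fallback"
  if (length(no_window) > 0 && nrow(genes) > 0) {
    by_chrom <- split(genes[, c("gene_id", "start", "end")], genes$chrom)
    for (i in no_window) {
      tab <- by_chrom[[snps$chrom[i]]]
      if (is.null(tab)) next
      assigned[[i]] <- nearest_flanking(snps$pos[i], tab)
    }
  }
  unplaced <- sum(lengths(assigned) == 0)
  if (unplaced > 0) {
    warning(sprintf("%d SNP(s) on chromosomes without protein-coding genes left unassigned",
                    unplaced))
  }
  data.frame(snp_id = snps$snp_id, rule = rule, genes = I(assigned))
}

# Nearest gene strictly left of pos and strictly right of pos; ties broken
# toward the smaller gene_id. Only reached when no gene overlaps the window,
# so no gene interval contains pos.
nearest_flanking <- function(pos, tab) {
  pick <- function(idx, dist) {
    if (length(idx) == 0) return(character(0))
    best <- idx[dist[idx] == min(dist[idx])]
    min(tab$gene_id[best])
  }
  left <- which(tab$end < pos)
  right <- which(tab$start > pos)
  dist <- pmin(abs(pos - tab$start), abs(pos - tab$end))
  sort(c(pick(left, dist), pick(right, dist)))
}

#' Map a single SNP to genes
#'
#' Single-record convenience wrapper around [map_snps_to_genes()].
#'
#' @param snp One-row SNP data.frame (or list with `snp_id`, `chrom`, `pos`).
#' @param genes Protein-coding gene annotation.
#' @param window_bp Window half-width in base pairs.
#' @return List with `snp_id`, `assigned_genes` (character) and `rule_used`.
#' @export
map_snp_to_genes <- function(snp, genes, window_bp) {
  df <- data.frame(snp_id = snp$snp_id, chrom = snp$chrom,
                   pos = snp$pos, p_value = snp$p_value %||% NA_real_)
  res <- map_snps_to_genes(df, genes, window_bp)
  list(snp_id = res$snp_id[1], assigned_genes = res$genes[[1]],
       rule_used = res$rule[1])
}

#' Select the top associated SNPs
#'
#' Keeps SNPs with p strictly below `p_threshold`, sorts ascending by p with
#' ties broken lexicographically by `snp_id`, and truncates to `top_count`.
#' Fewer rows are returned when fewer SNPs pass.
#'
#' @param snps SNP association data.frame.
#' @param top_count Maximum number of SNPs to keep.
#' @param p_threshold Strict upper bound on the association p-value.
#' @return The selected SNP rows, in selection order.
#' @export
select_top_snps <- function(snps, top_count, p_threshold) {
  stopifnot(top_count >= 1, p_threshold > 0)
  keep <- snps[snps$p_value < p_threshold, , drop = FALSE]
  keep <- keep[order(keep$p_value, keep$snp_id), , drop = FALSE]
  head(keep, top_count)
}

#' Build a deduplicated gene list from a SNP set
#'
#' Maps every SNP with [map_snps_to_genes()] and takes the union of the
#' assignments: a gene hit by several SNPs is counted once, so linkage
#' disequilibrium between nearby SNPs cannot inflate the list.
#'
#' @param snps SNP association data.frame.
#' @param genes Gene annotation; filtered to protein-coding internally.
#' @param window_bp Window half-width in base pairs.
#' @return Sorted character vector of unique gene ids.
#' @export
build_gene_list <- function(snps, genes, window_bp) {
  coding <- protein_coding(genes)
  assignments <- map_snps_to_genes(snps, coding, window_bp)
  sort(unique(as.character(unlist(assignments$genes, use.names = FALSE))))
}

#' Write SNP-to-gene assignments as a table
#'
#' @param assignments Data.frame from [map_snps_to_genes()].
#' @param path Output path; columns `snp_id`, `rule`, comma-joined `genes`.
#' @return `path`, invisibly.
#' @export
write_snp_assignments <- function(assignments, path) {
  out <- data.frame(
    snp_id = assignments$snp_id,
    rule = assignments$rule,
    genes = vapply(assignments$genes, paste, character(1), collapse = ",")
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
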