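# Shared fixtures and independent oracles, built in code at test time.

# Three-gene annotation used for the worked SNP-mapping examples.
abc_genes <- function() {
  data.frame(
    gene_id = c("A", "B", "C"),
    chrom = "chr1",
    start = c(10000L, 50000L, 120000L),
    end = c(15000L, 60000L, 130000L),
    biotype = "protein_coding"
  )
}

# Small hand-filled panel: `genes` x (cases + controls) x `regions`,
# constant value everywhere unless overridden afterwards.
tiny_panel <- function(genes = paste0("g", 1:4), n_cases = 2, n_controls = 3,
                       regions = c("DMV", "LCER", "SNGRA"), fill = 5) {
  subjects <- c(sprintf("case%02d", seq_len(n_cases)),
                sprintf("ctrl%02d", seq_len(n_controls)))
  group <- setNames(rep(c("case", "control"), c(n_cases, n_controls)),
                    subjects)
  values <- array(fill, dim = c(length(genes), length(subjects),
                                length(regions)),
                  dimnames = list(genes, subjects, regions))
  expression_panel(values, group)
}

# Scaled-down simulation for unit tests; keeps the planted structure.
# Extra arguments override the scaled defaults.
small_spec <- function(seed = 1L, ...) {
  args <- list(rng_seed = seed, n_chrom = 2L, n_genes = 300L,
               n_pathways = 20L, pathway_size_range = c(5L, 30L),
               planted_pathway_size = 15L, n_snps = 3000L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_spec, args)
}

# Brute-force all-pairs SNP-to-gene oracle: linear scan over every gene,
# independent of the interval-index implementation.
oracle_map_snp <- function(pos, chrom, genes, window_bp) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) {
    return(list(genes = character(0), rule = "nearest_fallback"))
  }
  in_window <- g$start <= pos + window_bp & g$end >= pos - window_bp
  if (any(in_window)) {
    return(list(genes = sort(g$gene_id[in_window]), rule = "window"))
  }
  dist <- pmin(abs(pos - g$start), abs(pos - g$end))
  pick_side <- function(side) {
    if (!any(side)) return(character(0))
    d <- dist[side]
    ids <- g$gene_id[side][d == min(d)]
    min(ids)
  }
  list(genes = sort(c(pick_side(g$end < pos), pick_side(g$start > pos))),
       rule = "nearest_fallback")
}

# Random mapping instance: up to `max_genes` (possibly overlapping) genes on
# two chromosomes and `max_snps` SNPs with a random window.
random_mapping_instance <- function(max_genes = 50, max_snps = 200) {
  n_g <- sample.int(max_genes, 1)
  n_s <- sample.int(max_snps, 1)
  start <- sample.int(200000L, n_g, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_g)),
    chrom = sample(c("chr1", "chr2"), n_g, replace = TRUE),
    start = start,
    end = start + sample.int(20000L, n_g, replace = TRUE),
    biotype = "protein_coding"
  )
  snps <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(n_s)),
    chrom = sample(c("chr1", "chr2"), n_s, replace = TRUE),
    pos = sample.int(250000L, n_s, replace = TRUE),
    p_value = runif(n_s)
  )
  list(genes = genes, snps = snps,
       window_bp = sample(c(0L, 500L, 5000L, 20000L), 1))
}

# Rational-arithmetic tail enumeration for the hypergeometric; exact in
# double precision for N <= 30.
oracle_hyper_tail <- function(N, K, n) {
  i <- 0:min(K, n)
  terms <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  rev(cumsum(rev(terms)))  # tail(k) for k = 0..min(K, n)
}
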