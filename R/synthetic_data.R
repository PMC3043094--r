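#' Simulation specification for the synthetic study
#'
#' Defines the generative model the pipeline is validated against. Defaults
#' describe the planted-signal study condition: 2,000 protein-coding genes on
#' 4 chromosomes, 200 pathways of which one ("PW001", 50 genes) carries the
#' planted signal, 20,000 GWAS SNPs whose p-values are Beta(a, 1) with
#' a = 0.2 near planted genes and uniform elsewhere, and a 5-region
#' expression panel for 7 cases and 4 controls in which planted genes gain
#' 1.0 log2 unit per Braak transition in cases only, over shared per-region
#' baseline offsets and Normal(0, 0.3) noise.
#'
#' Setting `gwas_effect_beta_a = 1` and `stage_shift_per_transition = 0`
#' yields a fully null dataset.
#'
#' @param rng_seed Master seed; each generator derives its own stream from it
#'   so, e.g., changing `n_snps` never perturbs the expression panel.
#' @param n_chrom Number of chromosomes.
#' @param n_genes Total genes, laid out left-to-right without overlap.
#' @param mean_gene_length_bp,mean_intergenic_gap_bp Means of the exponential
#'   length and gap distributions.
#' @param n_pathways Number of gene sets.
#' @param pathway_size_range Integer `c(min, max)`; non-planted pathway sizes
#'   are uniform on this range.
#' @param planted_pathways Character ids of pathways carrying planted signal.
#' @param planted_pathway_size Exact member count for each planted pathway.
#' @param n_snps Number of GWAS SNPs, placed uniformly over chromosome spans.
#' @param gwas_effect_beta_a Beta(a, 1) shape for p-values of SNPs within
#'   `window_bp` of a planted gene; `a < 1` enriches small p-values, `a = 1`
#'   is the uniform null.
#' @param window_bp Planting window around planted genes, matching the
#'   mapping window.
#' @param n_cases,n_controls Subject counts for the expression panel.
#' @param regions Ordered region labels (Braak order).
#' @param stage_shift_per_transition Case-only log2 shift gained by planted
#'   genes at each Braak transition.
#' @param noise_sd Standard deviation of the log2 measurement noise.
#' @param baseline_region_offsets Named per-region log2 offsets shared by all
#'   subjects (the "normal functional variation between brain regions" that
#'   the control adjustment removes).
#' @param baseline_mean,baseline_sd Per-gene log2 baseline distribution.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(rng_seed = 1L,
                            n_chrom = 4L,
                            n_genes = 2000L,
                            mean_gene_length_bp = 10000L,
                            mean_intergenic_gap_bp = 10000L,
                            n_pathways = 200L,
                            pathway_size_range = c(20L, 100L),
                            planted_pathways = "PW001",
                            planted_pathway_size = 50L,
                            n_snps = 20000L,
                            gwas_effect_beta_a = 0.2,
                            window_bp = 20000L,
                            n_cases = 7L,
                            n_controls = 4L,
                            regions = BRAAK_REGIONS,
                            stage_shift_per_transition = 1.0,
                            noise_sd = 0.3,
                            baseline_region_offsets = c(DMV = 0, LCER = 0.4,
                                                        SNGRA = -0.3,
                                                        PTMN = 0.2,
                                                        INSLA = -0.2),
                            baseline_mean = 8,
                            baseline_sd = 1.5) {
  spec <- list(
    rng_seed = as.integer(rng_seed), n_chrom = as.integer(n_chrom),
    n_genes = as.integer(n_genes),
    mean_gene_length_bp = as.numeric(mean_gene_length_bp),
    mean_intergenic_gap_bp = as.numeric(mean_intergenic_gap_bp),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    planted_pathways = as.character(planted_pathways),
    planted_pathway_size = as.integer(planted_pathway_size),
    n_snps = as.integer(n_snps),
    gwas_effect_beta_a = as.numeric(gwas_effect_beta_a),
    window_bp = as.integer(window_bp),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    regions = as.character(regions),
    stage_shift_per_transition = as.numeric(stage_shift_per_transition),
    noise_sd = as.numeric(noise_sd),
    baseline_region_offsets = baseline_region_offsets,
    baseline_mean = as.numeric(baseline_mean),
    baseline_sd = as.numeric(baseline_sd)
  )
  stopifnot(
    spec$n_genes >= 1, spec$n_chrom >= 1,
    spec$mean_gene_length_bp > 0, spec$mean_intergenic_gap_bp > 0,
    spec$n_pathways >= 1, length(spec$pathway_size_range) == 2,
    spec$pathway_size_range[1] >= 1,
    spec$pathway_size_range[1] <= spec$pathway_size_range[2],
    spec$pathway_size_range[2] <= spec$n_genes,
    spec$planted_pathway_size >= 1,
    spec$planted_pathway_size <= spec$n_genes,
    spec$n_snps >= 1,
    spec$gwas_effect_beta_a > 0, spec$gwas_effect_beta_a <= 1,
    spec$window_bp >= 0,
    spec$n_cases >= 1, spec$n_controls >= 2,
    length(spec$regions) >= 2, spec$noise_sd > 0,
    all(spec$regions %in% names(spec$baseline_region_offsets))
  )
  ids <- pathway_ids(spec)
  if (!all(spec$planted_pathways %in% c(ids, character(0)))) {
    stop("planted_pathways must be among the generated pathway ids (",
         ids[1], " .. ", ids[length(ids)], ")")
  }
  class(spec) <- "simulation_spec"
  spec
}

pathway_ids <- function(spec) sprintf("PW%03d", seq_len(spec$n_pathways))

# Fixed per-generator seed offsets: one independent stream per generator.
SEED_OFFSET <- c(annotation = 101L, pathways = 202L, gwas = 303L,
                 expression = 404L)

#' Generate a non-overlapping gene annotation
#'
#' Genes are laid left-to-right per chromosome with exponentially distributed
#' lengths and intergenic gaps (1-based inclusive coordinates, minimum length
#' and gap of 1 bp). All generated genes are protein-coding. Deterministic
#' given `spec$rng_seed`.
#'
#' @param spec A `simulation_spec`.
#' @return Gene annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `biotype`).
#' @export
gen_annotation <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$rng_seed + SEED_OFFSET[["annotation"]], {
    per_chrom <- diff(round(seq(0, spec$n_genes, length.out = spec$n_chrom + 1)))
    lens <- pmax(1, round(rexp(spec$n_genes, 1 / spec$mean_gene_length_bp)))
    gaps <- pmax(1, round(rexp(spec$n_genes, 1 / spec$mean_intergenic_gap_bp)))
    chrom <- rep(sprintf("chr%d", seq_len(spec$n_chrom)), per_chrom)
    start <- integer(spec$n_genes)
    end <- integer(spec$n_genes)
    idx <- 1L
    for (c_i in seq_len(spec$n_chrom)) {
      cursor <- 0L
      for (j in seq_len(per_chrom[c_i])) {
        start[idx] <- cursor + gaps[idx] + 1L
        end[idx] <- start[idx] + lens[idx] - 1L
        cursor <- end[idx]
        idx <- idx + 1L
      }
    }
    data.frame(
      gene_id = sprintf("g%05d", seq_len(spec$n_genes)),
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      biotype = "protein_coding"
    )
  })
}

#' Generate a pathway collection over a gene annotation
#'
#' Non-planted pathway sizes are uniform on `spec$pathway_size_range`;
#' planted pathways have exactly `spec$planted_pathway_size` members. Members
#' are drawn without replacement within a pathway and independently across
#' pathways, so genes may belong to several pathways. Deterministic given
#' `spec$rng_seed`.
#'
#' @param spec A `simulation_spec`.
#' @param genes Gene annotation from [gen_annotation()].
#' @return A `gene_set_collection`.
#' @export
gen_pathways <- function(spec, genes) {
  stopifnot(inherits(spec, "simulation_spec"))
  ids <- pathway_ids(spec)
  with_seed(spec$rng_seed + SEED_OFFSET[["pathways"]], {
    size_pool <- seq.int(spec$pathway_size_range[1],
                         spec$pathway_size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), spec$n_pathways,
                                  replace = TRUE)]
    sizes[ids %in% spec$planted_pathways] <- spec$planted_pathway_size
    sets <- setNames(
      lapply(sizes, function(k) sample(genes$gene_id, k)),
      ids
    )
    gene_set_collection(sets, setNames(sprintf("pathway %s", ids), ids))
  })
}

planted_genes <- function(spec, pathways) {
  unique(unlist(pathways$sets[spec$planted_pathways], use.names = FALSE))
}

#' Generate GWAS summary statistics with planted association
#'
#' SNPs are placed uniformly over each chromosome's span (counts
#' proportional to span). A SNP whose `window_bp` neighbourhood touches a
#' planted-pathway gene draws its p-value from Beta(a, 1) with
#' `a = spec$gwas_effect_beta_a`; all other SNPs draw from Uniform(0, 1).
#' Deterministic given `spec$rng_seed`.
#'
#' @param spec A `simulation_spec`.
#' @param genes Gene annotation.
#' @param pathways `gene_set_collection` from [gen_pathways()].
#' @return SNP association data.frame (`snp_id`, `chrom`, `pos`, `p_value`).
#' @export
gen_gwas <- function(spec, genes, pathways) {
  stopifnot(inherits(spec, "simulation_spec"))
  spans <- tapply(as.numeric(genes$end), genes$chrom, max)
  chroms <- names(spans)
  with_seed(spec$rng_seed + SEED_OFFSET[["gwas"]], {
    n_per <- as.vector(round(spec$n_snps * spans / sum(spans)))
    n_per[length(n_per)] <- spec$n_snps - sum(n_per[-length(n_per)])
    chrom <- rep(chroms, n_per)
    pos <- unlist(lapply(seq_along(chroms), function(i) {
      sort(sample.int(spans[[i]], n_per[i], replace = TRUE))
    }), use.names = FALSE)
    pg <- planted_genes(spec, pathways)
    near <- rep(FALSE, length(pos))
    if (length(pg) > 0) {
      pg_tab <- genes[genes$gene_id %in% pg, , drop = FALSE]
      hits <- findOverlaps(
        GRanges(chrom, IRanges(pos - spec$window_bp, pos + spec$window_bp)),
        GRanges(pg_tab$chrom, IRanges(pg_tab$start, pg_tab$end))
      )
      near[unique(queryHits(hits))] <- TRUE
    }
    p <- runif(spec$n_snps)
    if (any(near) && spec$gwas_effect_beta_a < 1) {
      p[near] <- rbeta(sum(near), spec$gwas_effect_beta_a, 1)
    }
    # Beta/Uniform draws can round to exactly 0 in double precision; keep p
    # in (0, 1] as the association-table contract requires.
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    data.frame(snp_id = sprintf("rs%06d", seq_len(spec$n_snps)),
               chrom = chrom, pos = as.integer(pos), p_value = p)
  })
}

#' Generate a staged expression panel with planted regional drift
#'
#' Each value is
#' `baseline(gene) + region_offset(region) + shift + Normal(0, noise_sd)`,
#' where the shift term is `stage_index(region) * stage_shift_per_transition`
#' for planted genes in case subjects (stage index 0 for the first Braak
#' region) and 0 otherwise. Region offsets are shared by all subjects, so the
#' control-average adjustment removes them. Deterministic given
#' `spec$rng_seed`.
#'
#' @param spec A `simulation_spec`.
#' @param genes Gene annotation.
#' @param pathways `gene_set_collection`.
#' @return An `expression_panel`.
#' @export
gen_expression <- function(spec, genes, pathways) {
  stopifnot(inherits(spec, "simulation_spec"))
  subjects <- c(sprintf("case%02d", seq_len(spec$n_cases)),
                sprintf("ctrl%02d", seq_len(spec$n_controls)))
  group <- setNames(rep(c("case", "control"),
                        c(spec$n_cases, spec$n_controls)), subjects)
  regions <- spec$regions
  gid <- genes$gene_id
  pg <- planted_genes(spec, pathways)
  with_seed(spec$rng_seed + SEED_OFFSET[["expression"]], {
    baseline <- rnorm(length(gid), spec$baseline_mean, spec$baseline_sd)
    values <- array(rnorm(length(gid) * length(subjects) * length(regions),
                          0, spec$noise_sd),
                    dim = c(length(gid), length(subjects), length(regions)),
                    dimnames = list(gid, subjects, regions))
    values <- values + baseline  # recycles over subjects and regions
    for (r_i in seq_along(regions)) {
      values[, , r_i] <- values[, , r_i] +
        spec$baseline_region_offsets[[regions[r_i]]]
      if (length(pg) > 0 && spec$stage_shift_per_transition != 0) {
        shift <- (r_i - 1) * spec$stage_shift_per_transition
        values[gid %in% pg, group == "case", r_i] <-
          values[gid %in% pg, group == "case", r_i] + shift
      }
    }
    expression_panel(values, group)
  })
}

#' Generate the full synthetic study
#'
#' Convenience wrapper running all four generators.
#'
#' @param spec A `simulation_spec`.
#' @return List with `annotation`, `pathways`, `snps` and `panel`.
#' @export
gen_study <- function(spec) {
  annotation <- gen_annotation(spec)
  pathways <- gen_pathways(spec, annotation)
  list(annotation = annotation,
       pathways = pathways,
       snps = gen_gwas(spec, annotation, pathways),
       panel = gen_expression(spec, annotation, pathways))
}

#' Write a synthetic study in the pipeline's input formats
#'
#' Emits exactly the files the readers in this package consume, so fixtures
#' are round-trip tested: `annotation.tsv`, `pathways.gmt`, `snps.tsv`,
#' `expression_cases.tsv`, `expression_controls.tsv`.
#'
#' @param study List from [gen_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    snps = file.path(dir, "snps.tsv"),
    cases = file.path(dir, "expression_cases.tsv"),
    controls = file.path(dir, "expression_controls.tsv")
  )
  write_gene_table(study$annotation, paths[["annotation"]])
  write_gmt(study$pathways, paths[["pathways"]])
  write_snp_table(study$snps, paths[["snps"]])
  write_expression_panel(study$panel, paths[["cases"]], paths[["controls"]])
  paths
}
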