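#' Run the integrative pathway analysis end to end
#'
#' Executes the full convergence workflow on in-memory inputs: SNP-to-gene
#' mapping builds the GWAS query (top SNPs) and reference (all SNPs) gene
#' lists; the subtraction design produces the merged differential gene list
#' against the panel-gene universe; both lists are tested for pathway
#' over-representation; and the two per-pathway p-values are combined by
#' Fisher's method with Bonferroni correction over the pathways testable in
#' both studies. Both convergence views are produced: the overlap of the two
#' significant sets and the ranked meta-analysis table.
#'
#' @param annotation Gene annotation data.frame.
#' @param snps SNP association data.frame.
#' @param pathways A `gene_set_collection`.
#' @param panel An `expression_panel`.
#' @param config A `pipeline_config`.
#' @return List with elements `reference_genes`, `top_snps`, `query_genes`,
#'   `gwas_enrichment`, `subtraction`, `gene_lists`, `expr_enrichment`,
#'   `gwas_significant`, `expr_significant`, `overlap`, `meta`, `config`.
#' @export
run_pipeline <- function(annotation, snps, pathways, panel,
                         config = pipeline_config()) {
  stopifnot(inherits(pathways, "gene_set_collection"),
            inherits(panel, "expression_panel"),
            inherits(config, "pipeline_config"))
  reference_genes <- build_gene_list(snps, annotation, config$window_bp)
  top_snps <- select_top_snps(snps, config$top_snp_count,
                              config$snp_p_threshold)
  query_genes <- build_gene_list(top_snps, annotation, config$window_bp)
  gwas_enrichment <- test_pathways(query_genes, reference_genes, pathways)

  subtraction <- subtraction_table(panel, config)
  gene_lists <- collect_gene_lists(subtraction)
  expr_enrichment <- test_pathways(gene_lists$merged, panel$genes, pathways)

  gwas_significant <- significant_pathways(gwas_enrichment,
                                           config$pathway_alpha)
  expr_significant <- significant_pathways(expr_enrichment,
                                           config$pathway_alpha)
  list(
    reference_genes = reference_genes,
    top_snps = top_snps,
    query_genes = query_genes,
    gwas_enrichment = gwas_enrichment,
    subtraction = subtraction,
    gene_lists = gene_lists,
    expr_enrichment = expr_enrichment,
    gwas_significant = gwas_significant,
    expr_significant = expr_significant,
    overlap = overlap_report(gwas_significant, expr_significant),
    meta = meta_analysis(gwas_enrichment, expr_enrichment),
    config = config
  )
}

#' Run the pipeline from files on disk, writing all stage outputs
#'
#' File-based wrapper over [run_pipeline()]. Any stage failure aborts with
#' the stage name and cause. A run manifest (configuration snapshot, input
#' MD5 digests, stage timings in seconds, output paths, package version) is
#' written as JSON at the end; identical inputs and configuration reproduce
#' byte-identical stage outputs.
#'
#' @param paths Named list/vector with entries `annotation`, `snps`,
#'   `pathways` (GMT), `cases`, `controls`.
#' @param config A `pipeline_config`.
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly.
#' @export
run_pipeline_files <- function(paths, config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    list(value = value, seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }
  timings <- list()

  inputs <- stage("read_inputs", {
    for (key in c("annotation", "snps", "pathways", "cases", "controls")) {
      if (is.null(paths[[key]]) || !file.exists(paths[[key]])) {
        stop("missing input file for '", key, "'")
      }
    }
    list(annotation = read_gene_table(paths[["annotation"]]),
         snps = read_snp_table(paths[["snps"]]),
         pathways = read_gmt(paths[["pathways"]]),
         panel = read_expression_panel(paths[["cases"]], paths[["controls"]]))
  })
  timings$read_inputs <- inputs$seconds

  run <- stage("pipeline", run_pipeline(inputs$value$annotation,
                                        inputs$value$snps,
                                        inputs$value$pathways,
                                        inputs$value$panel, config))
  timings$pipeline <- run$seconds
  res <- run$value

  outputs <- stage("write_outputs", {
    out <- c(
      reference_genes = file.path(out_dir, "gwas_reference_genes.txt"),
      query_genes = file.path(out_dir, "gwas_query_genes.txt"),
      gwas_enrichment = file.path(out_dir, "gwas_enrichment.tsv"),
      subtraction = file.path(out_dir, "subtraction_table.tsv"),
      merged_genes = file.path(out_dir, "expr_merged_genes.txt"),
      expr_enrichment = file.path(out_dir, "expr_enrichment.tsv"),
      overlap = file.path(out_dir, "overlap_report.txt"),
      meta = file.path(out_dir, "meta_table.tsv")
    )
    write_gene_list(res$reference_genes, out[["reference_genes"]])
    write_gene_list(res$query_genes, out[["query_genes"]])
    write_enrichment(res$gwas_enrichment, out[["gwas_enrichment"]])
    write_subtraction_table(res$subtraction, out[["subtraction"]])
    write_gene_list(res$gene_lists$merged, out[["merged_genes"]])
    write_enrichment(res$expr_enrichment, out[["expr_enrichment"]])
    write_overlap_report(res$overlap, out[["overlap"]])
    write_meta_table(res$meta, out[["meta"]])
    out
  })
  timings$write_outputs <- outputs$seconds

  manifest <- list(
    tool = "pathmeta",
    version = as.character(utils::packageVersion("pathmeta")),
    config = unclass(config),
    inputs = as.list(tools::md5sum(unlist(paths))),
    timings_seconds = timings,
    outputs = as.list(outputs$value)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, manifest_path)
  invisible(c(manifest, list(result = res)))
}

#' One-command synthetic demonstration run
#'
#' Generates the default planted-signal study (one pathway carrying signal in
#' both the GWAS and the expression arm), writes its input files, runs the
#' full pipeline on them, prints the top-10 ranked meta table and the
#' overlap counts, and writes the run manifest.
#'
#' @param seed Integer seed for the synthetic study.
#' @param out_dir Output directory.
#' @param spec Optional `simulation_spec` overriding the default (its
#'   `rng_seed` is replaced by `seed`).
#' @param quiet Suppress the printed summary.
#' @return The manifest (with the in-memory stage results attached), invisibly.
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("pathmeta_demo"),
                     spec = NULL, quiet = FALSE) {
  spec <- spec %||% simulation_spec()
  spec$rng_seed <- as.integer(seed)
  study <- gen_study(spec)
  in_dir <- file.path(out_dir, "inputs")
  paths <- write_study(study, in_dir)
  config <- pipeline_config(rng_seed = spec$rng_seed,
                            window_bp = spec$window_bp)
  manifest <- run_pipeline_files(as.list(paths), config,
                                 file.path(out_dir, "outputs"))
  if (!quiet) {
    meta <- manifest$result$meta
    cat("Top pathways by combined p-value (M =", attr(meta, "M"), "):\n")
    print(head(meta[, c("pathway_id", "p_gwas", "p_expr", "p_meta",
                        "p_corrected", "rank")], 10), row.names = FALSE)
    ov <- manifest$result$overlap
    cat(sprintf(
      "\nOver-represented pathways: GWAS %d, expression %d, common %d (%s)\n",
      ov$n_gwas_sig, ov$n_expr_sig, ov$n_common,
      paste(ov$common_ids, collapse = ", ")))
  }
  invisible(manifest)
}

#' Reported meta-analysis table from the published PD case study
#'
#' The top-20 pathway table of a published Parkinson's disease integration of
#' GWAS and regional expression, with the reported combined (Fisher) and
#' Bonferroni-corrected p-values. Used to infer the Bonferroni multiplier the
#' published analysis applied (see [infer_bonferroni_multiplier()]): the
#' printed pairs are consistent with multiplying by 201, the number of
#' pathways testable in both of its studies, rather than the full 205-pathway
#' human catalogue.
#'
#' @return Data.frame with columns `pathway`, `p_meta`, `p_corrected` in
#'   reported rank order.
#' @export
reported_pd_meta <- function() {
  path <- system.file("extdata", "pd_meta_reported.tsv", package = "pathmeta",
                      mustWork = TRUE)
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
}
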