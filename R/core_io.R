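#' Pipeline configuration
#'
#' Bundles the thresholds used across the pipeline. Defaults reproduce the
#' published analysis settings: a 20 kbp SNP-to-gene window on either side of
#' each SNP, the 5,000 most significant SNPs at p < 0.01, a 1.6-fold
#' expression change gate, Benjamini-Hochberg q < 0.05 for differential
#' calls, and p <= 0.05 for calling a pathway over-represented.
#'
#' @param window_bp Window half-width in base pairs for SNP-to-gene mapping.
#' @param top_snp_count Maximum number of top SNPs forming the GWAS query.
#' @param snp_p_threshold SNPs must have association p strictly below this to
#'   enter the query.
#' @param fold_change_threshold Linear-scale fold change a differential call
#'   must reach; applied as `|adjusted delta| >= log2(fold_change_threshold)`
#'   on the log2 expression scale. Must exceed 1.
#' @param q_threshold Benjamini-Hochberg q-value cutoff for differential calls.
#' @param pathway_alpha Significance level for over-represented pathways
#'   (inclusive: p <= alpha).
#' @param rng_seed Integer seed forwarded to any stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_bp = 20000L,
                            top_snp_count = 5000L,
                            snp_p_threshold = 0.01,
                            fold_change_threshold = 1.6,
                            q_threshold = 0.05,
                            pathway_alpha = 0.05,
                            rng_seed = 1L) {
  cfg <- list(
    window_bp = as.integer(window_bp),
    top_snp_count = as.integer(top_snp_count),
    snp_p_threshold = as.numeric(snp_p_threshold),
    fold_change_threshold = as.numeric(fold_change_threshold),
    q_threshold = as.numeric(q_threshold),
    pathway_alpha = as.numeric(pathway_alpha),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$window_bp >= 0, cfg$top_snp_count >= 1,
    cfg$snp_p_threshold > 0, cfg$snp_p_threshold <= 1,
    cfg$fold_change_threshold > 1,
    cfg$q_threshold > 0, cfg$q_threshold <= 1,
    cfg$pathway_alpha > 0, cfg$pathway_alpha <= 1
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Path to a flat YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a SNP association table
#'
#' Expects tab-separated text with header columns `snp_id`, `chrom`, `pos`
#' (1-based base pairs) and `p_value`. Row order is preserved.
#'
#' @param path Path to the table.
#' @return A data.frame with one row per SNP.
#' @export
read_snp_table <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  required <- c("snp_id", "chrom", "pos", "p_value")
  if (!all(required %in% names(df))) {
    stop("SNP table must have columns: ", paste(required, collapse = ", "))
  }
  df <- df[, required]
  if (nrow(df) == 0) {
    return(data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), p_value = numeric()))
  }
  pos <- suppressWarnings(as.numeric(df$pos))
  p <- suppressWarnings(as.numeric(df$p_value))
  bad <- which(is.na(pos) | pos < 1 | pos != round(pos) |
                 is.na(p) | p <= 0 | p > 1)
  if (length(bad) > 0) {
    stop(sprintf("malformed SNP record at data row %d (pos=%s, p_value=%s)",
                 bad[1], df$pos[bad[1]], df$p_value[bad[1]]))
  }
  if (anyDuplicated(df$snp_id)) {
    stop("duplicate snp_id: ", df$snp_id[anyDuplicated(df$snp_id)])
  }
  data.frame(snp_id = df$snp_id, chrom = df$chrom,
             pos = as.integer(round(pos)), p_value = p)
}

#' Write a SNP association table
#'
#' @param snps Data.frame as returned by [read_snp_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects tab-separated text with header columns `gene_id`, `chrom`,
#' `start`, `end` (1-based, inclusive) and `biotype`. Coordinates follow the
#' dbSNP/ENSEMBL convention: 1-based and inclusive at both ends.
#'
#' @param path Path to the table.
#' @return A data.frame of gene models.
#' @export
read_gene_table <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  required <- c("gene_id", "chrom", "start", "end", "biotype")
  if (!all(required %in% names(df))) {
    stop("gene table must have columns: ", paste(required, collapse = ", "))
  }
  df <- df[, required]
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1 |
                 df$start > df$end)
  if (length(bad) > 0) {
    stop(sprintf("malformed gene interval at data row %d (gene %s)",
                 bad[1], df$gene_id[bad[1]]))
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id: ", df$gene_id[anyDuplicated(df$gene_id)])
  }
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$biotype <- as.character(df$biotype)
  df
}

#' Write a gene annotation table
#'
#' @param genes Data.frame of gene models.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep only protein-coding gene models
#'
#' Query and reference gene lists consider protein-coding genes only.
#'
#' @param genes Gene annotation data.frame.
#' @return The protein-coding subset.
#' @export
protein_coding <- function(genes) {
  genes[genes$biotype == "protein_coding", , drop = FALSE]
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors; names are pathway ids,
#'   elements are member gene ids (deduplicated, non-empty).
#' @param descriptions Optional named character vector of pathway names; any
#'   pathway without one gets its id as description.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), length(sets) > 0 || is.list(sets))
  ids <- names(sets)
  if (is.null(ids) && length(sets) > 0) stop("sets must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id: ", ids[anyDuplicated(ids)])
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0)) {
    stop("empty member set for pathway ",
         ids[which(lengths(sets) == 0)[1]])
  }
  desc <- setNames(rep(NA_character_, length(sets)), ids)
  if (!is.null(descriptions)) desc[names(descriptions)] <- descriptions
  desc[is.na(desc)] <- ids[is.na(desc)]
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d pathways, member counts %s\n",
              length(x$sets),
              if (length(x$sets) > 0)
                paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, fields `set_id`, `description`,
#' then one or more member gene ids, tab-separated. Duplicate members within
#' a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate set_id in GMT: ", ids[anyDuplicated(ids)])
  }
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), ids)
  sets <- setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
  gene_set_collection(sets, desc)
}

#' Write gene sets to a GMT file
#'
#' Round-trips with [read_gmt()].
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- names(collection$sets)
  lines <- vapply(ids, function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Braak-ordered brain regions used by default
#'
#' Dorsal motor nucleus of the vagus (stage 1), locus ceruleus (stage 2),
#' substantia nigra (stage 3), putamen (stage 4) and insula (stage 5).
#'
#' @export
BRAAK_REGIONS <- c("DMV", "LCER", "SNGRA", "PTMN", "INSLA")

#' Construct an expression panel
#'
#' A panel holds log2 expression values for every (gene, subject, region)
#' triple, with subjects labelled case or control and regions kept in Braak
#' order. Values must be complete: the within-subject subtraction design is
#' undefined when a subject lacks a region, so missing data are an error,
#' never imputed.
#'
#' @param values Numeric 3-d array indexed gene x subject x region, with
#'   dimnames.
#' @param group Named character vector (`"case"`/`"control"`) over subjects.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(values, group) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  dn <- dimnames(values)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1)))) {
    stop("values must have complete dimnames (genes, subjects, regions)")
  }
  if (anyNA(values)) stop("expression panel contains missing values")
  subjects <- dn[[2]]
  regions <- dn[[3]]
  if (length(regions) < 2) stop("panel needs at least 2 regions")
  group <- group[subjects]
  if (anyNA(group) || !all(group %in% c("case", "control"))) {
    stop("group must label every subject as 'case' or 'control'")
  }
  if (sum(group == "case") < 1) stop("panel needs at least 1 case")
  if (sum(group == "control") < 2) {
    stop("panel needs at least 2 controls (control variance is estimated)")
  }
  structure(list(values = values, genes = dn[[1]], subjects = subjects,
                 group = group, regions = regions),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf(
    "expression_panel: %d genes, %d cases + %d controls, regions %s\n",
    length(x$genes), sum(x$group == "case"), sum(x$group == "control"),
    paste(x$regions, collapse = " > ")))
  invisible(x)
}

parse_panel_matrix <- function(path, regions) {
  df <- read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  cols <- colnames(df)
  parts <- strsplit(cols, ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("expression columns must be labelled subject:region (", path, ")")
  }
  subj <- vapply(parts, `[[`, character(1), 1L)
  reg <- vapply(parts, `[[`, character(1), 2L)
  if (!all(reg %in% regions)) {
    stop("unknown region label(s): ",
         paste(unique(reg[!reg %in% regions]), collapse = ", "))
  }
  for (s in unique(subj)) {
    missing <- setdiff(regions, reg[subj == s])
    if (length(missing) > 0) {
      stop(sprintf("subject %s lacks region %s in %s", s, missing[1], path))
    }
  }
  list(mat = as.matrix(df), subj = subj, reg = reg)
}

#' Read case and control expression matrices into a panel
#'
#' Each file is a tab-separated matrix with gene ids in the first column and
#' data columns labelled `subject:region`; every subject must have a column
#' for every configured region. Genes present in only one of the two files
#' are dropped with a message reporting the count.
#'
#' @param case_path,control_path Paths to the case and control matrices.
#' @param regions Ordered region labels (Braak order); defaults to
#'   [BRAAK_REGIONS].
#' @return An `expression_panel`.
#' @export
read_expression_panel <- function(case_path, control_path,
                                  regions = BRAAK_REGIONS) {
  ca <- parse_panel_matrix(case_path, regions)
  co <- parse_panel_matrix(control_path, regions)
  shared <- intersect(rownames(ca$mat), rownames(co$mat))
  dropped <- length(union(rownames(ca$mat), rownames(co$mat))) - length(shared)
  if (dropped > 0) {
    message(sprintf("read_expression_panel: dropped %d gene(s) absent from one file",
                    dropped))
  }
  if (length(shared) == 0) stop("no genes shared between case and control files")
  subjects <- c(unique(ca$subj), unique(co$subj))
  group <- setNames(rep(c("case", "control"),
                        c(length(unique(ca$subj)), length(unique(co$subj)))),
                    subjects)
  values <- array(NA_real_,
                  dim = c(length(shared), length(subjects), length(regions)),
                  dimnames = list(shared, subjects, regions))
  fill <- function(src) {
    for (j in seq_along(src$subj)) {
      values[, src$subj[j], src$reg[j]] <<- src$mat[shared, j]
    }
  }
  fill(ca)
  fill(co)
  expression_panel(values, group)
}

#' Write an expression panel as case and control matrices
#'
#' Inverse of [read_expression_panel()].
#'
#' @param panel An `expression_panel`.
#' @param case_path,control_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression_panel <- function(panel, case_path, control_path) {
  stopifnot(inherits(panel, "expression_panel"))
  write_side <- function(subjects, path) {
    cols <- as.vector(t(outer(subjects, panel$regions, paste, sep = ":")))
    mat <- matrix(NA_real_, nrow = length(panel$genes), ncol = length(cols),
                  dimnames = list(panel$genes, cols))
    for (s in subjects) {
      for (r in panel$regions) {
        mat[, paste(s, r, sep = ":")] <- panel$values[, s, r]
      }
    }
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_side(panel$subjects[panel$group == "case"], case_path)
  write_side(panel$subjects[panel$group == "control"], control_path)
  invisible(c(case_path, control_path))
}

#' Write a gene list, one id per line
#'
#' @param genes Character vector of gene ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(sort(unique(as.character(genes))), path)
  invisible(path)
}
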