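#' Preprocessing configuration for an SCT experiment
#'
#' Defaults follow the published pipeline: genes expressed in fewer than 20
#' cells are dropped in every dataset; the human configuration additionally
#' keeps only cells expressing more human than mouse genes (the CITE-seq
#' spike-in design), drops cells expressing fewer than 200 genes, and keeps
#' highly variable genes with the dispersion filter at
#' `min_mean = 0.0125`, `max_mean = 3`, `min_disp = -0.15`.
#'
#' @param min_cells_per_gene genes expressed (non-zero) in fewer cells than
#'   this are excluded.
#' @param min_genes_per_cell cells expressing fewer genes are discarded
#'   (0 disables the filter).
#' @param species_select apply the human-vs-mouse cell selection first.
#' @param species_prefixes the two gene-name prefixes (kept species first).
#' @param hvg apply the dispersion-based highly-variable-gene filter.
#' @param hvg_min_mean,hvg_max_mean,hvg_min_disp dispersion-filter gates on
#'   the log-scale gene mean and the bin-normalized dispersion.
#' @param hvg_normalize scale each cell to the median library size before
#'   computing dispersions (used only inside the HVG step).
#' @param n_top_markers marker genes kept per population by
#'   [rank_marker_genes()].
#' @param de_method one-vs-rest test for marker ranking: Welch t
#'   (`"t-test"`, default) or Wilcoxon rank-sum (`"wilcoxon"`).
#' @return a list of class `ifc_preprocess_config`.
#' @export
preprocess_config <- function(min_cells_per_gene = 20L,
                              min_genes_per_cell = 0L,
                              species_select = FALSE,
                              species_prefixes = c("HUMAN_", "MOUSE_"),
                              hvg = FALSE,
                              hvg_min_mean = 0.0125,
                              hvg_max_mean = 3,
                              hvg_min_disp = -0.15,
                              hvg_normalize = TRUE,
                              n_top_markers = 100L,
                              de_method = c("t-test", "wilcoxon")) {
  de_method <- match.arg(de_method)
  stopifnot(min_cells_per_gene >= 0, min_genes_per_cell >= 0,
            n_top_markers >= 1, length(species_prefixes) == 2)
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_genes_per_cell = as.integer(min_genes_per_cell),
                 species_select = isTRUE(species_select),
                 species_prefixes = species_prefixes,
                 hvg = isTRUE(hvg),
                 hvg_min_mean = hvg_min_mean, hvg_max_mean = hvg_max_mean,
                 hvg_min_disp = hvg_min_disp,
                 hvg_normalize = isTRUE(hvg_normalize),
                 n_top_markers = as.integer(n_top_markers),
                 de_method = de_method),
            class = "ifc_preprocess_config")
}

#' Human-dataset preprocessing configuration
#'
#' [preprocess_config()] with the human CITE-seq settings switched on
#' (species selection, 200-gene cell filter, dispersion HVG filter).
#' @export
human_preprocess_config <- function() {
  preprocess_config(min_genes_per_cell = 200L, species_select = TRUE,
                    hvg = TRUE)
}

#' Keep cells of the first species and drop the other species' genes
#'
#' The CITE-seq human dataset carries mouse spike-in cells; a cell is kept
#' when it expresses strictly more genes of the first prefix than of the
#' second ("expressed" = non-zero count; ties are dropped as ambiguous
#' doublets). Rows of the second species are removed from the output.
#'
#' @param counts an [count_matrix()] object whose gene ids all start with
#'   one of the two prefixes.
#' @param prefixes character(2): keep-species prefix, drop-species prefix.
#' @return filtered [count_matrix()].
#' @export
select_species_cells <- function(counts, prefixes = c("HUMAN_", "MOUSE_")) {
  stopifnot(inherits(counts, "ifc_counts"), length(prefixes) == 2)
  is1 <- startsWith(counts$gene_ids, prefixes[1])
  is2 <- startsWith(counts$gene_ids, prefixes[2])
  if (any(!is1 & !is2))
    stop("gene without species prefix: ",
         counts$gene_ids[which(!is1 & !is2)[1]])
  nz <- counts$values > 0
  n1 <- colSums(nz[is1, , drop = FALSE])
  n2 <- colSums(nz[is2, , drop = FALSE])
  keep <- n1 > n2
  out <- counts$values[is1, keep, drop = FALSE]
  rownames(out) <- sub(paste0("^", prefixes[1]), "",
                       counts$gene_ids[is1])
  count_matrix(out)
}

#' Drop genes expressed in too few cells
#'
#' @param counts an [count_matrix()] object.
#' @param min_cells keep genes with non-zero counts in at least this many
#'   cells (a gene seen in exactly `min_cells` cells is kept).
#' @return filtered [count_matrix()].
#' @export
filter_genes_min_cells <- function(counts, min_cells = 20L) {
  stopifnot(inherits(counts, "ifc_counts"), min_cells >= 0)
  keep <- rowSums(counts$values > 0) >= min_cells
  count_matrix(counts$values[keep, , drop = FALSE])
}

#' Drop cells expressing too few genes
#'
#' @param counts an [count_matrix()] object.
#' @param min_genes keep cells with at least this many non-zero genes.
#' @return filtered [count_matrix()].
#' @export
filter_cells_min_genes <- function(counts, min_genes = 200L) {
  stopifnot(inherits(counts, "ifc_counts"), min_genes >= 0)
  keep <- colSums(counts$values > 0) >= min_genes
  count_matrix(counts$values[, keep, drop = FALSE])
}

# Dispersion statistics of the 20-bin recipe, on the same scale the gates
# are applied to (log1p gene mean, log dispersion, bin-z-scored).
hvg_dispersion_stats <- function(counts, normalize = TRUE, n_bins = 20L) {
  x <- counts$values
  storage.mode(x) <- "double"
  if (normalize) {
    lib <- colSums(x)
    if (any(lib == 0)) stop("cell with zero total count: ",
                            counts$cell_ids[which(lib == 0)[1]])
    x <- sweep(x, 2, lib / median(lib), "/")
  }
  # recipe operates on expm1 of the log-data, i.e. the (normalized) counts
  gmean <- rowMeans(x)
  gvar <- apply(x, 1, var)
  gmean_safe <- ifelse(gmean == 0, 1e-12, gmean)
  disp <- gvar / gmean_safe
  disp_log <- ifelse(disp == 0, NA_real_, log(disp))
  mean_log <- log1p(gmean)
  bin <- cut(mean_log, breaks = n_bins)
  bin_mu <- tapply(disp_log, bin, mean, na.rm = TRUE)
  bin_sd <- tapply(disp_log, bin, sd, na.rm = TRUE)
  # singleton (or zero-spread) bins: z-score against the raw dispersion
  single <- is.na(bin_sd) | bin_sd == 0
  bin_sd[single] <- bin_mu[single]
  bin_mu[single] <- 0
  disp_norm <- (disp_log - bin_mu[bin]) / bin_sd[bin]
  data.frame(gene = counts$gene_ids, mean = mean_log,
             dispersion = disp_log, dispersion_norm = as.numeric(disp_norm))
}

#' Keep highly variable genes by binned dispersion
#'
#' The dispersion recipe of the published pipeline: cells are scaled to the
#' median library size (optional), per-gene dispersion = variance / mean of
#' the scaled counts, the log-dispersion is z-scored within 20 equal-width
#' bins of the `log1p` gene mean, and a gene is kept when
#' `min_mean < mean < max_mean` (log scale) and its normalized dispersion
#' exceeds `min_disp`.
#'
#' @param counts an [count_matrix()] object.
#' @param min_mean,max_mean open interval for the `log1p` gene mean.
#' @param min_disp minimum bin-normalized dispersion (exclusive).
#' @param normalize scale cells to the median library size first.
#' @return filtered [count_matrix()].
#' @export
select_highly_variable_genes <- function(counts, min_mean = 0.0125,
                                         max_mean = 3, min_disp = -0.15,
                                         normalize = TRUE) {
  stopifnot(inherits(counts, "ifc_counts"))
  st <- hvg_dispersion_stats(counts, normalize = normalize)
  keep <- !is.na(st$dispersion_norm) &
    st$mean > min_mean & st$mean < max_mean &
    st$dispersion_norm > min_disp
  if (!any(keep))
    stop("no genes pass the dispersion filter; relax min_mean/max_mean/",
         "min_disp")
  count_matrix(counts$values[keep, , drop = FALSE])
}

#' Natural-log transform counts
#'
#' Elementwise `x -> ln(1 + x)`, so zeros map to zero and the transform is
#' defined on all non-negative counts.
#'
#' @param counts an [count_matrix()] object (or any non-negative matrix).
#' @return an [expression_matrix()] with cells in rows and genes in columns.
#' @export
log_transform <- function(counts) {
  x <- if (inherits(counts, "ifc_counts")) counts$values else as.matrix(counts)
  if (any(x < 0)) stop("log_transform: negative input")
  expression_matrix(t(log1p(x)))
}

welch_t_stats <- function(x_in, x_out) {
  n1 <- ncol(x_in); n2 <- ncol(x_out)
  m1 <- rowMeans(x_in); m2 <- rowMeans(x_out)
  v1 <- apply(x_in, 1, var); v2 <- apply(x_out, 1, var)
  denom <- sqrt(v1 / n1 + v2 / n2)
  num <- m1 - m2
  tt <- num / denom
  tt[denom == 0 & num == 0] <- 0
  tt[denom == 0 & num != 0] <- sign(num[denom == 0 & num != 0]) * Inf
  tt
}

wilcoxon_z_stats <- function(x_in, x_out) {
  n1 <- ncol(x_in); n2 <- ncol(x_out)
  vapply(seq_len(nrow(x_in)), function(g) {
    r <- rank(c(x_in[g, ], x_out[g, ]))
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    # tie-corrected normal approximation
    tie <- table(r)
    sg2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tie^3 - tie) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sg2 == 0) 0 else (w - mu) / sqrt(sg2)
  }, numeric(1))
}

#' Rank differentially expressed marker genes per population
#'
#' One-vs-rest differential expression on the log-transformed matrix: for
#' each population, every gene is scored against all remaining cells and
#' the top `n_top` genes by descending statistic are reported. The default
#' statistic is the Welch t; a tie-corrected Wilcoxon rank-sum z is
#' available. Ties on the statistic break by gene id for determinism.
#'
#' @param expr an [expression_matrix()] (cells x genes, log scale).
#' @param labels character vector of population labels, one per cell
#'   (or an `ifc_labels` object from [apply_gates()]).
#' @param n_top genes kept per population.
#' @param method `"t-test"` (Welch) or `"wilcoxon"`.
#' @param exclude populations not ranked (default: the reserved `"other"`
#'   label is still ranked; pass `"other"` to drop it).
#' @return a list of class `ifc_marker_ranking`: per population a
#'   `data.frame(gene, score)` sorted by descending score.
#' @export
rank_marker_genes <- function(expr, labels, n_top = 100L,
                              method = c("t-test", "wilcoxon"),
                              exclude = character(0)) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "ifc_expr"))
  if (inherits(labels, "ifc_labels")) labels <- labels$labels
  labels <- as.character(labels)
  if (length(labels) != nrow(expr$values))
    stop("rank_marker_genes: one label per cell required")
  pops <- setdiff(sort(unique(labels)), exclude)
  if (length(pops) < 2)
    stop("rank_marker_genes: need at least 2 populations")
  tab <- table(labels)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("population with fewer than 2 cells: ", small[1])
  xg <- t(expr$values)  # genes x cells
  rankings <- lapply(pops, function(p) {
    x_in <- xg[, labels == p, drop = FALSE]
    x_out <- xg[, labels != p, drop = FALSE]
    score <- if (method == "t-test") welch_t_stats(x_in, x_out)
             else wilcoxon_z_stats(x_in, x_out)
    ord <- order(-score, expr$target_names)
    head(data.frame(gene = expr$target_names[ord], score = score[ord],
                    row.names = NULL), n_top)
  })
  names(rankings) <- pops
  structure(list(populations = pops, rankings = rankings,
                 method = method, n_top = as.integer(n_top)),
            class = "ifc_marker_ranking")
}

#' @export
print.ifc_marker_ranking <- function(x, ...) {
  cat("<ifc_marker_ranking> ", length(x$populations), " populations, top ",
      x$n_top, " genes each (", x$method, ")\n", sep = "")
  for (p in x$populations)
    cat("  ", p, ": ", paste(head(x$rankings[[p]]$gene, 5), collapse = ", "),
        ", ...\n", sep = "")
  invisible(x)
}

#' Union of the top marker genes across populations
#'
#' @param ranking an `ifc_marker_ranking`.
#' @param n_top optionally restrict to the first `n_top` genes per
#'   population before taking the union.
#' @return character vector of gene ids.
#' @export
marker_gene_union <- function(ranking, n_top = NULL) {
  stopifnot(inherits(ranking, "ifc_marker_ranking"))
  unique(unlist(lapply(ranking$rankings, function(df)
    head(df$gene, if (is.null(n_top)) nrow(df) else n_top))))
}

#' Run the full SCT preprocessing pipeline
#'
#' Applies the published composition in its fixed order: species selection
#' and the minimum-genes cell filter (human configuration), the dispersion
#' HVG filter (human configuration), then for every dataset the
#' minimum-cells gene filter, `log1p` transformation, marker normalization,
#' gating, and one-vs-rest marker-gene ranking.
#'
#' @param counts raw [count_matrix()].
#' @param markers raw [marker_table()] for the same cells (optional; needed
#'   for gating/ranking).
#' @param config an [preprocess_config()].
#' @param gates an [gate_set()] for population labelling (optional).
#' @return a list with `counts` (filtered), `expr` (log, cells x genes),
#'   `markers` (normalized, filtered cells), `labels`, `ranking` (the last
#'   two `NULL` without `gates`).
#' @export
preprocess_sct <- function(counts, markers = NULL,
                           config = preprocess_config(), gates = NULL) {
  stopifnot(inherits(counts, "ifc_counts"),
            inherits(config, "ifc_preprocess_config"))
  if (config$species_select)
    counts <- select_species_cells(counts, config$species_prefixes)
  if (config$min_genes_per_cell > 0)
    counts <- filter_cells_min_genes(counts, config$min_genes_per_cell)
  if (config$hvg)
    counts <- select_highly_variable_genes(
      counts, config$hvg_min_mean, config$hvg_max_mean,
      config$hvg_min_disp, normalize = config$hvg_normalize)
  counts <- filter_genes_min_cells(counts, config$min_cells_per_gene)
  expr <- log_transform(counts)
  markers_norm <- labels <- ranking <- NULL
  if (!is.null(markers)) {
    stopifnot(inherits(markers, "ifc_markers"))
    idx <- match(counts$cell_ids, markers$cell_ids)
    if (anyNA(idx))
      stop("preprocess_sct: marker table is missing cells: ",
           counts$cell_ids[which(is.na(idx))[1]])
    markers_norm <- normalize_markers(
      marker_table(markers$values[idx, , drop = FALSE]))
    if (!is.null(gates)) {
      labels <- apply_gates(markers_norm, gates)
      ranking <- rank_marker_genes(expr, labels,
                                   n_top = config$n_top_markers,
                                   method = config$de_method)
    }
  }
  list(counts = counts, expr = expr, markers = markers_norm,
       labels = labels, ranking = ranking)
}

#' Append surface-protein targets to an expression matrix
#'
#' The human configuration predicts surface CD4 alongside gene expression;
#' this helper appends the chosen ADT columns (by default `log1p`
#' transformed like the genes) as extra targets.
#'
#' @param expr an [expression_matrix()].
#' @param adt an [marker_table()] of surface-protein counts/intensities
#'   covering the same cells.
#' @param targets ADT columns to append (default `"CD4"`).
#' @param log log-transform the appended columns.
#' @param prefix prefix for the new target names (default `"surface_"`).
#' @return the extended [expression_matrix()].
#' @export
append_surface_targets <- function(expr, adt, targets = "CD4", log = TRUE,
                                   prefix = "surface_") {
  stopifnot(inherits(expr, "ifc_expr"), inherits(adt, "ifc_markers"))
  idx <- match(expr$cell_ids, adt$cell_ids)
  if (anyNA(idx)) stop("append_surface_targets: ADT table missing cells")
  miss <- setdiff(targets, adt$marker_names)
  if (length(miss)) stop("ADT markers not found: ",
                         paste(miss, collapse = ", "))
  extra <- adt$values[idx, targets, drop = FALSE]
  if (log) {
    if (any(extra < 0)) stop("negative ADT values cannot be log-transformed")
    extra <- log1p(extra)
  }
  colnames(extra) <- paste0(prefix, targets)
  expression_matrix(cbind(expr$values, extra))
}

#' Recompute the preprocessing cell/gene counts on the published data
#'
#' Runs the exact published filter cascade on locally downloaded copies of
#' the source datasets and reports the resulting dataset sizes. The human
#' input is the GEO supplementary count file
#' `GSE100866_CBMC_8K_13AB_10X-RNA_umi.csv.gz`; the mouse input is a
#' gene-by-cell CSV export of the myeloid-progenitor UMI matrix. Neither
#' file ships with the package (they are hundreds of MB); place them under
#' `data_dir` first.
#'
#' @param data_dir directory holding the downloaded files.
#' @param human_file,mouse_file file names inside `data_dir`.
#' @return `data.frame` with one row per dataset and columns
#'   `n_cells`, `n_genes`.
#' @export
reproduce_preprocessing_counts <- function(
    data_dir = "data-raw",
    human_file = "GSE100866_CBMC_8K_13AB_10X-RNA_umi.csv.gz",
    mouse_file = "mouse_myeloid_umi.csv.gz") {
  out <- list()
  hp <- file.path(data_dir, human_file)
  if (!file.exists(hp))
    stop("human count file not found: ", hp,
         " (download the GEO supplementary file into ", data_dir, ")")
  h <- preprocess_sct(read_gene_by_cell_csv(hp),
                      config = human_preprocess_config())
  out$human <- dim(h$counts)
  mp <- file.path(data_dir, mouse_file)
  if (!file.exists(mp))
    stop("mouse count file not found: ", mp)
  m <- preprocess_sct(read_gene_by_cell_csv(mp),
                      config = preprocess_config())
  out$mouse <- dim(m$counts)
  data.frame(dataset = names(out),
             n_genes = vapply(out, function(d) as.numeric(d[1]), 0),
             n_cells = vapply(out, function(d) as.numeric(d[2]), 0),
             row.names = NULL)
}
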