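# column-wise Pearson between two aligned matrices; NA where either column
# has zero variance
colwise_pearson <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  sa <- sqrt(colSums(A^2))
  sb <- sqrt(colSums(B^2))
  r <- colSums(A * B) / (sa * sb)
  r[sa == 0 | sb == 0] <- NA_real_
  r
}

colwise_spearman <- function(A, B) {
  colwise_pearson(apply(A, 2, rank), apply(B, 2, rank))
}

align_pair <- function(true, pred, targets = NULL) {
  stopifnot(inherits(true, "ifc_expr"), inherits(pred, "ifc_expr"))
  idx <- match(true$cell_ids, pred$cell_ids)
  if (anyNA(idx)) stop("prediction is missing cells: ",
                       true$cell_ids[which(is.na(idx))[1]])
  if (is.null(targets))
    targets <- intersect(true$target_names, pred$target_names)
  miss <- setdiff(targets, intersect(true$target_names, pred$target_names))
  if (length(miss)) stop("targets absent from true/pred: ",
                         paste(head(miss, 3), collapse = ", "))
  list(true = true$values[, targets, drop = FALSE],
       pred = pred$values[idx, targets, drop = FALSE],
       cells = true$cell_ids, targets = targets)
}

#' Per-cell agreement between true and predicted expression
#'
#' For every cell, Pearson and Spearman correlation and RMSE between the
#' true and predicted values across a gene subset (typically the union of
#' the top population marker genes). Cells whose true or predicted vector
#' has zero variance get an undefined correlation; these are excluded from
#' the reported medians and counted.
#'
#' @param true,pred [expression_matrix()] objects sharing cells/targets.
#' @param gene_subset targets to evaluate over (>= 3); default all shared.
#' @return list of class `ifc_metrics`: `per_cell` data frame, `medians`
#'   named vector, `n_undefined`, `gene_subset`.
#' @export
per_cell_metrics <- function(true, pred, gene_subset = NULL) {
  al <- align_pair(true, pred, gene_subset)
  if (length(al$targets) < 3)
    stop("per_cell_metrics: need at least 3 genes, got ",
         length(al$targets))
  tA <- t(al$true)
  tB <- t(al$pred)
  pearson <- colwise_pearson(tA, tB)
  spearman <- colwise_spearman(tA, tB)
  rmse <- sqrt(colMeans((tA - tB)^2))
  med <- c(pearson = median(pearson, na.rm = TRUE),
           spearman = median(spearman, na.rm = TRUE),
           rmse = median(rmse))
  structure(list(per_cell = data.frame(cell = al$cells, pearson = pearson,
                                       spearman = spearman, rmse = rmse,
                                       row.names = NULL),
                 medians = med,
                 n_undefined = sum(is.na(pearson)),
                 gene_subset = al$targets),
            class = "ifc_metrics")
}

#' @export
print.ifc_metrics <- function(x, ...) {
  cat("<ifc_metrics> ", nrow(x$per_cell), " cells over ",
      length(x$gene_subset), " genes; median Pearson ",
      round(x$medians["pearson"], 3), ", Spearman ",
      round(x$medians["spearman"], 3), ", RMSE ",
      round(x$medians["rmse"], 3),
      if (x$n_undefined > 0) paste0(" (", x$n_undefined,
                                    " undefined cells excluded)"),
      "\n", sep = "")
  invisible(x)
}

#' Per-gene correlation between true and predicted expression
#'
#' @param true,pred [expression_matrix()] objects sharing cells/targets.
#' @param cell_subset optional cell ids to restrict to.
#' @return data frame with `gene`, `pearson`, `spearman` (NA where a gene
#'   has zero variance in either matrix).
#' @export
per_gene_metrics <- function(true, pred, cell_subset = NULL) {
  al <- align_pair(true, pred)
  A <- al$true
  B <- al$pred
  if (!is.null(cell_subset)) {
    keep <- al$cells %in% cell_subset
    if (!any(keep)) stop("per_gene_metrics: empty cell subset")
    A <- A[keep, , drop = FALSE]
    B <- B[keep, , drop = FALSE]
  }
  data.frame(gene = al$targets,
             pearson = colwise_pearson(A, B),
             spearman = colwise_spearman(A, B), row.names = NULL)
}

#' Per-tree uncertainty of the per-gene correlation
#'
#' For each gene, the Pearson correlation between every individual tree's
#' prediction and the truth, then the standard deviation of those
#' correlations over the ensemble (population form, denominator
#' `n_trees`). Trees with an undefined correlation for a gene are dropped
#' from that gene's standard deviation.
#'
#' @param per_tree `cells x targets x trees` array from
#'   [predict_expression()] with `per_tree = TRUE`.
#' @param true an [expression_matrix()] aligned on the same cells.
#' @param gene_subset targets to evaluate (default: all in `per_tree`).
#' @return data frame with `gene`, `sd_pearson`, `n_trees_defined`.
#' @export
per_tree_uncertainty <- function(per_tree, true, gene_subset = NULL) {
  stopifnot(length(dim(per_tree)) == 3, inherits(true, "ifc_expr"))
  genes <- dimnames(per_tree)[[2]]
  if (is.null(gene_subset)) gene_subset <- intersect(genes,
                                                     true$target_names)
  idx <- match(dimnames(per_tree)[[1]], true$cell_ids)
  if (anyNA(idx)) stop("per_tree_uncertainty: cells missing from truth")
  K <- dim(per_tree)[3]
  tv <- true$values[idx, gene_subset, drop = FALSE]
  rmat <- vapply(seq_len(K), function(k) {
    pk <- per_tree[, , k]
    colwise_pearson(tv, pk[, gene_subset, drop = FALSE])
  }, numeric(length(gene_subset)))
  rmat <- matrix(rmat, nrow = length(gene_subset))
  pop_sd <- apply(rmat, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) return(NA_real_)
    sqrt(mean((r - mean(r))^2))
  })
  data.frame(gene = gene_subset, sd_pearson = pop_sd,
             n_trees_defined = apply(rmat, 1, function(r) sum(!is.na(r))),
             row.names = NULL)
}

#' Population-average expression profiles
#'
#' One row per population, one column per marker gene; entries are the
#' arithmetic mean expression over the population's cells.
#'
#' @param expr an [expression_matrix()].
#' @param labels population labels (character or `ifc_labels`), one per
#'   cell of `expr`.
#' @param marker_genes genes to profile (default: all targets).
#' @return numeric matrix `populations x genes`.
#' @export
population_profiles <- function(expr, labels, marker_genes = NULL) {
  stopifnot(inherits(expr, "ifc_expr"))
  if (inherits(labels, "ifc_labels")) labels <- labels$labels
  labels <- as.character(labels)
  if (length(labels) != nrow(expr$values))
    stop("population_profiles: one label per cell required")
  if (is.null(marker_genes)) marker_genes <- expr$target_names
  miss <- setdiff(marker_genes, expr$target_names)
  if (length(miss)) stop("unknown genes: ", paste(head(miss, 3),
                                                  collapse = ", "))
  pops <- sort(unique(labels))
  out <- t(vapply(pops, function(p)
    colMeans(expr$values[labels == p, marker_genes, drop = FALSE]),
    numeric(length(marker_genes))))
  dimnames(out) <- list(pops, marker_genes)
  out
}

#' Transcriptional similarity between populations
#'
#' Pairwise Pearson correlation between the population-average marker-gene
#' profiles, optionally with Fisher-transform confidence intervals (the
#' effective n is the number of genes in the profile vectors).
#'
#' @param profiles `populations x genes` matrix from
#'   [population_profiles()].
#' @param conf confidence level for the intervals; `NULL` skips them.
#' @param n effective sample size for the intervals (defaults to the number
#'   of profile genes).
#' @return list of class `ifc_similarity`: symmetric correlation matrix
#'   `r` with unit diagonal, plus `lo`/`hi` CI matrices when requested.
#' @export
population_similarity <- function(profiles, conf = 0.95, n = NULL) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2)
  r <- stats::cor(t(profiles))
  diag(r) <- 1
  out <- list(r = r, populations = rownames(profiles))
  if (!is.null(conf)) {
    if (is.null(n)) n <- ncol(profiles)
    lo <- hi <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
    for (i in seq_len(nrow(r)))
      for (j in seq_len(ncol(r)))
        if (i != j) {
          ci <- fisher_ci(r[i, j], n, conf)
          lo[i, j] <- ci[1]
          hi[i, j] <- ci[2]
        }
    diag(lo) <- diag(hi) <- 1
    out$lo <- lo
    out$hi <- hi
    out$conf <- conf
    out$n <- n
  }
  structure(out, class = "ifc_similarity")
}

#' @export
print.ifc_similarity <- function(x, ...) {
  cat("<ifc_similarity> ", nrow(x$r), " populations\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' Fisher-transform confidence interval for a Pearson correlation
#'
#' `tanh(atanh(r) -+ z / sqrt(n - 3))` with `z` the `(1 + conf) / 2`
#' normal quantile.
#'
#' @param r correlation; `|r| = 1` yields the degenerate interval
#'   `(r, r)` with a warning.
#' @param n sample size (>= 4).
#' @param confidence confidence level.
#' @return numeric `(low, high)`.
#' @export
fisher_ci <- function(r, n, confidence = 0.95) {
  stopifnot(length(r) == 1, abs(r) <= 1)
  if (n < 4) stop("fisher_ci: need n >= 4")
  if (abs(r) == 1) {
    warning("fisher_ci: |r| = 1, returning a degenerate interval")
    return(c(low = r, high = r))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm((1 + confidence) / 2)
  c(low = tanh(z - q * se), high = tanh(z + q * se))
}

#' Is population A significantly more similar to B than to C?
#'
#' The comparison logic used on the similarity heatmaps: TRUE iff the
#' lower confidence bound of (A, B) exceeds the upper bound of (A, C).
#'
#' @param sim an `ifc_similarity` with confidence intervals.
#' @param a,b,c population names.
#' @return logical.
#' @export
significantly_more_similar <- function(sim, a, b, c) {
  stopifnot(inherits(sim, "ifc_similarity"))
  if (is.null(sim$lo)) stop("similarity was computed without intervals")
  sim$lo[a, b] > sim$hi[a, c]
}

#' Bootstrap standard deviation of a Pearson correlation
#'
#' Resamples paired observations with replacement, computes the
#' correlation per resample, and reports the population standard deviation
#' over resamples. Degenerate (zero-variance) resamples are skipped and
#' counted.
#'
#' @param true_vec,pred_vec aligned numeric vectors (n >= 10).
#' @param n_boot bootstrap iterations (published protocol: 10000).
#' @param seed integer seed.
#' @return list with `sd`, `r` (full-sample correlation), `n_degenerate`.
#' @export
bootstrap_corr_std <- function(true_vec, pred_vec, n_boot = 10000L,
                               seed = 1L) {
  n <- length(true_vec)
  stopifnot(n == length(pred_vec), n >= 10)
  rs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      x <- true_vec[i]
      y <- pred_vec[i]
      if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
    }, numeric(1))
  })
  ok <- rs[!is.na(rs)]
  list(sd = sqrt(mean((ok - mean(ok))^2)),
       r = cor(true_vec, pred_vec),
       n_degenerate = sum(is.na(rs)))
}
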