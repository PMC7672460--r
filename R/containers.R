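#' Construct a gene-by-cell UMI count matrix
#'
#' The raw SCT input: non-negative integer counts with genes in rows and
#' cells in columns.
#'
#' @param values integer matrix, genes x cells, non-negative.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   `colnames(values)`).
#' @return an object of class `ifc_counts` with fields `values`, `gene_ids`,
#'   `cell_ids`.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) && nrow(values) == 0) gene_ids <- character(0)
  if (is.null(cell_ids) && ncol(values) == 0) cell_ids <- character(0)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("count_matrix: gene_ids and cell_ids are required")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("count_matrix: ", length(gene_ids), " gene_ids for ",
         nrow(values), " rows")
  if (length(cell_ids) != ncol(values))
    stop("count_matrix: ", length(cell_ids), " cell_ids for ",
         ncol(values), " columns")
  if (anyDuplicated(gene_ids))
    stop("count_matrix: duplicate gene id: ",
         gene_ids[anyDuplicated(gene_ids)])
  if (anyDuplicated(cell_ids))
    stop("count_matrix: duplicate cell id: ",
         cell_ids[anyDuplicated(cell_ids)])
  if (anyNA(values) || !is.numeric(values))
    stop("count_matrix: counts must be numeric and non-missing")
  if (any(values < 0))
    stop("count_matrix: negative counts")
  if (any(values != round(values)))
    stop("count_matrix: counts must be integers")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "ifc_counts")
}

#' @export
print.ifc_counts <- function(x, ...) {
  cat("<ifc_counts> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells; ", round(100 * mean(x$values > 0), 1),
      "% entries non-zero\n", sep = "")
  invisible(x)
}

#' @export
dim.ifc_counts <- function(x) dim(x$values)

#' @export
as.matrix.ifc_counts <- function(x, ...) x$values

#' Construct a cell-by-marker intensity table
#'
#' Continuous surface-marker intensities, either raw or min-max normalized
#' to \[0, 1\] (see [normalize_markers()]). Rows are cells, columns markers.
#'
#' @param values numeric matrix, cells x markers.
#' @param marker_names,cell_ids identifiers; default to dimnames.
#' @param normalized logical; `TRUE` only when every column has been mapped
#'   to \[0, 1\] with both bounds attained.
#' @param bounds optional list with numeric vectors `min` and `max` (one per
#'   marker) recording the normalization parameters for inversion.
#' @return an object of class `ifc_markers`.
#' @export
marker_table <- function(values, marker_names = colnames(values),
                         cell_ids = rownames(values), normalized = FALSE,
                         bounds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(marker_names))
    marker_names <- paste0("marker", seq_len(ncol(values)))
  if (is.null(cell_ids))
    stop("marker_table: cell_ids are required")
  cell_ids <- as.character(cell_ids)
  marker_names <- as.character(marker_names)
  if (length(cell_ids) != nrow(values) ||
      length(marker_names) != ncol(values))
    stop("marker_table: id lengths do not match the value matrix")
  if (anyDuplicated(cell_ids))
    stop("marker_table: duplicate cell id: ",
         cell_ids[anyDuplicated(cell_ids)])
  if (anyNA(values))
    stop("marker_table: missing marker values")
  if (isTRUE(normalized)) {
    rng <- apply(values, 2, range)
    if (any(rng[1, ] < 0) || any(rng[2, ] > 1))
      stop("marker_table: normalized=TRUE but values fall outside [0, 1]")
  }
  dimnames(values) <- list(cell_ids, marker_names)
  structure(list(values = values, marker_names = marker_names,
                 cell_ids = cell_ids, normalized = isTRUE(normalized),
                 bounds = bounds),
            class = "ifc_markers")
}

#' @export
print.ifc_markers <- function(x, ...) {
  cat("<ifc_markers> ", nrow(x$values), " cells x ",
      paste(x$marker_names, collapse = ", "),
      if (x$normalized) " (normalized)" else " (raw)", "\n", sep = "")
  invisible(x)
}

#' @export
dim.ifc_markers <- function(x) dim(x$values)

#' @export
as.matrix.ifc_markers <- function(x, ...) x$values

#' Construct a cell-by-target expression matrix
#'
#' Real-valued (typically `log1p`-transformed) expression with cells in rows.
#' Targets are genes, optionally extended with surface-protein targets such
#' as CD4 in the human configuration.
#'
#' @param values numeric matrix, cells x targets.
#' @param cell_ids,target_names identifiers; default to dimnames.
#' @return an object of class `ifc_expr`.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              target_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids) && nrow(values) == 0) cell_ids <- character(0)
  if (is.null(target_names) && ncol(values) == 0)
    target_names <- character(0)
  if (is.null(cell_ids) || is.null(target_names))
    stop("expression_matrix: cell_ids and target_names are required")
  cell_ids <- as.character(cell_ids)
  target_names <- as.character(target_names)
  if (length(cell_ids) != nrow(values) ||
      length(target_names) != ncol(values))
    stop("expression_matrix: id lengths do not match the value matrix")
  if (anyDuplicated(cell_ids) || anyDuplicated(target_names))
    stop("expression_matrix: duplicate cell or target ids")
  dimnames(values) <- list(cell_ids, target_names)
  structure(list(values = values, cell_ids = cell_ids,
                 target_names = target_names),
            class = "ifc_expr")
}

#' @export
print.ifc_expr <- function(x, ...) {
  cat("<ifc_expr> ", nrow(x$values), " cells x ", ncol(x$values),
      " targets\n", sep = "")
  invisible(x)
}

#' @export
dim.ifc_expr <- function(x) dim(x$values)

#' @export
as.matrix.ifc_expr <- function(x, ...) x$values

#' Construct a stack of single-channel 16-bit brightfield images
#'
#' @param pixels integer array `n x height x width` with values in
#'   \[0, 65535\]. The published export format is 32 x 32.
#' @param cell_ids one id per image.
#' @return an object of class `ifc_images`.
#' @export
image_stack <- function(pixels, cell_ids = NULL) {
  if (length(dim(pixels)) != 3)
    stop("image_stack: pixels must be an n x height x width array")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 65535))
    stop("image_stack: pixel values must lie in [0, 65535]")
  if (any(pixels != round(pixels)))
    stop("image_stack: pixel values must be integers (16-bit raw)")
  storage.mode(pixels) <- "integer"
  n <- dim(pixels)[1]
  if (is.null(cell_ids)) cell_ids <- paste0("img", seq_len(n))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n)
    stop("image_stack: ", length(cell_ids), " cell_ids for ", n, " images")
  structure(list(pixels = pixels, cell_ids = cell_ids),
            class = "ifc_images")
}

#' @export
print.ifc_images <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<ifc_images> ", d[1], " images, ", d[2], "x", d[3],
      ", 16-bit\n", sep = "")
  invisible(x)
}

#' @export
dim.ifc_images <- function(x) dim(x$pixels)
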