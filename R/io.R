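# fread with transparent gzip (decompressed through a base connection so
# no optional helper package is needed)
read_csv_table <- function(path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    inp <- gzfile(path, "rb")
    out <- file(tmp, "wb")
    while (length(chunk <- readBin(inp, "raw", 8L * 1024L * 1024L)) > 0)
      writeBin(chunk, out)
    close(inp)
    close(out)
    path <- tmp
  }
  data.table::fread(path, header = TRUE, sep = ",",
                    colClasses = list(character = 1),
                    data.table = FALSE, showProgress = FALSE)
}

#' Read a gene-by-cell count CSV (GEO supplementary-file dialect)
#'
#' Parses count matrices laid out like the CITE-seq supplementary files
#' (`*_umi.csv.gz`): first column gene names, header row cell barcodes,
#' integer counts in the body. Gzip is handled transparently.
#'
#' @param path path to a `.csv` or `.csv.gz` file.
#' @param transpose if `TRUE` the file is cell x gene and is transposed on
#'   read; gene/cell roles in the returned object are unchanged.
#' @return an [count_matrix()] object.
#' @export
read_gene_by_cell_csv <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- read_csv_table(path)
  if (ncol(dt) < 2) stop("no cells in ", path)
  row_ids <- dt[[1]]
  body <- dt[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop("non-numeric count in ", path, " at row ", row_ids[bad],
           ", column ", colnames(body)[j])
    }
  }
  values <- as.matrix(body)
  rownames(values) <- row_ids
  if (transpose) values <- t(values)
  count_matrix(values)
}

#' Write a count matrix in the gene-by-cell CSV dialect
#'
#' @param counts an [count_matrix()] object.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_gene_by_cell_csv <- function(counts, path) {
  stopifnot(inherits(counts, "ifc_counts"))
  df <- data.frame(gene = counts$gene_ids, counts$values,
                   check.names = FALSE)
  data.table::fwrite(df, path, compress = if (grepl("\\.gz$", path))
    "gzip" else "none")
  invisible(path)
}

#' Read a cell-by-marker intensity CSV
#'
#' Cells in rows (first column = cell id), one column per marker.
#'
#' @param path CSV path.
#' @return an [marker_table()] object (raw, `normalized = FALSE`).
#' @export
read_marker_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- read_csv_table(path)
  if (ncol(dt) < 2) stop("no marker columns in ", path)
  values <- as.matrix(dt[, -1, drop = FALSE])
  rownames(values) <- dt[[1]]
  marker_table(values)
}

#' Write a cell-by-marker intensity CSV
#'
#' @param markers an [marker_table()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(markers, path) {
  stopifnot(inherits(markers, "ifc_markers"))
  df <- data.frame(cell = markers$cell_ids, markers$values,
                   check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read single-channel 16-bit TIFF images into a stack
#'
#' Each file must be one 16-bit grayscale frame of identical spatial size
#' (the published export format is 32 x 32). Cell ids default to file
#' basenames without extension.
#'
#' @param paths character vector of TIFF paths, in the desired stack order.
#' @param cell_ids optional manifest of ids overriding the basenames.
#' @return an [image_stack()] object.
#' @export
read_tiff_stack <- function(paths, cell_ids = NULL) {
  if (length(paths) == 0) stop("read_tiff_stack: no paths given")
  imgs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    img <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(img)) == 3) {
      if (dim(img)[3] != 1)
        stop("not single-channel: ", p)
      img <- img[, , 1]
    }
    img
  })
  d1 <- dim(imgs[[1]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d1))
      stop("image shape ", paste(dim(imgs[[i]]), collapse = "x"),
           " != ", paste(d1, collapse = "x"), " in ", paths[i])
    if (max(imgs[[i]]) > 65535 || min(imgs[[i]]) < 0)
      stop("not a 16-bit image: ", paths[i])
  }
  pixels <- array(0L, c(length(imgs), d1[1], d1[2]))
  for (i in seq_along(imgs)) pixels[i, , ] <- imgs[[i]]
  if (is.null(cell_ids))
    cell_ids <- sub("\\.[^.]*$", "", basename(paths))
  image_stack(pixels, cell_ids)
}

#' Write an image stack as one 16-bit TIFF per image
#'
#' @param stack an [image_stack()] object.
#' @param dir output directory (created if missing); files are named
#'   `<cell_id>.tif`.
#' @return the written paths, invisibly.
#' @export
write_tiff_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "ifc_images"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(stack$cell_ids, ".tif"))
  for (i in seq_along(paths)) {
    # tiff::writeTIFF takes [0,1] doubles; 16 bits => quantum of 1/65535
    tiff::writeTIFF(stack$pixels[i, , ] / 65535, paths[i],
                    bits.per.sample = 16)
  }
  invisible(paths)
}

#' Write and read predicted expression matrices
#'
#' Plain-text persistence of an [expression_matrix()]: a CSV with cell ids
#' in the first column, written with full double precision so the round
#' trip is lossless to 1e-12.
#'
#' @param pred an [expression_matrix()] object; `NaN`/`NA` entries are
#'   rejected.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  stopifnot(inherits(pred, "ifc_expr"))
  if (anyNA(pred$values))
    stop("write_predictions: NaN/NA entries are not allowed")
  # fwrite emits shortest-round-trip doubles, so the CSV is lossless
  df <- data.frame(cell = pred$cell_ids, pred$values, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = 1),
                          data.table = FALSE, showProgress = FALSE)
  values <- as.matrix(dt[, -1, drop = FALSE])
  if (nrow(dt) == 0)
    values <- matrix(numeric(0), 0, ncol(dt) - 1,
                     dimnames = list(NULL, colnames(dt)[-1]))
  rownames(values) <- dt[[1]]
  expression_matrix(values)
}
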