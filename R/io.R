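#' Read a 10x-style triplet directory into a count matrix
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` (optionally
#' `.gz`-compressed) in `dir_path`. The on-disk matrix follows the 10x
#' convention (genes x cells); the returned matrix is always oriented
#' cells x genes with barcode row names and gene-id column names.
#'
#' @param dir_path Directory containing the triplet.
#' @return A list with `counts` (sparse `dgCMatrix`, cells x genes),
#'   `features` (data.frame with `gene_id`, `gene_name` and, when present,
#'   `chromosome`) and `gene_chromosome` (named vector or `NULL`).
#' @export
read_10x <- function(dir_path) {
  locate <- function(base) {
    for (f in file.path(dir_path, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop("missing ", base, "(.gz) in ", dir_path, call. = FALSE)
  }
  mtx <- locate("matrix.mtx")
  m <- Matrix::readMM(if (grepl("\\.gz$", mtx)) gzfile(mtx) else mtx)
  feats <- read.delim(locate("features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  barcodes <- read.delim(locate("barcodes.tsv"), header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (nrow(feats) != nrow(m))
    stop("features.tsv has ", nrow(feats), " rows but matrix has ",
         nrow(m), " genes", call. = FALSE)
  if (length(barcodes) != ncol(m))
    stop("barcodes.tsv has ", length(barcodes), " rows but matrix has ",
         ncol(m), " cells", call. = FALSE)
  if (any(m@x != floor(m@x)) || any(m@x < 0))
    stop("matrix.mtx contains non-integer or negative entries", call. = FALSE)
  gene_ids <- as.character(feats[[1]])
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(barcodes)) stop("duplicate cell barcodes", call. = FALSE)
  counts <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(counts) <- list(barcodes, gene_ids)
  features <- data.frame(
    gene_id = gene_ids,
    gene_name = if (ncol(feats) >= 2) as.character(feats[[2]]) else gene_ids,
    stringsAsFactors = FALSE)
  gene_chromosome <- NULL
  if (ncol(feats) >= 3) {
    features$chromosome <- as.character(feats[[3]])
    gene_chromosome <- setNames(features$chromosome, gene_ids)
  }
  list(counts = counts, features = features, gene_chromosome = gene_chromosome)
}

#' Write a count matrix as a 10x-style triplet
#'
#' @param counts Sparse or dense cells x genes integer matrix with dimnames.
#' @param dir_path Output directory (created if missing).
#' @param gene_chromosome Optional named gene -> chromosome vector, written
#'   as the third features column.
#' @return `dir_path`, invisibly.
#' @export
write_10x <- function(counts, dir_path, gene_chromosome = NULL) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::t(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"))
  Matrix::writeMM(m, file.path(dir_path, "matrix.mtx"))
  feats <- data.frame(gene_id = colnames(counts), gene_name = colnames(counts),
                      stringsAsFactors = FALSE)
  if (!is.null(gene_chromosome))
    feats$chromosome <- unname(gene_chromosome[colnames(counts)])
  write.table(feats, file.path(dir_path, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(counts), file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

#' Read or write per-cell metadata
#'
#' The metadata table carries one row per barcode with at least `barcode`,
#' `sample`, `genotype` and `batch` columns (plus `cell_type` once assigned).
#'
#' @param meta A data.frame of per-cell metadata.
#' @param path TSV file path.
#' @return The data.frame (read) or `path` invisibly (write).
#' @export
write_cell_metadata <- function(meta, path) write_tsv(meta, path)

#' @rdname write_cell_metadata
#' @export
read_cell_metadata <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read or write named reference gene sets as JSON
#'
#' @param sets Named list of character gene vectors.
#' @param path JSON file path.
#' @return The named list (read) or `path` invisibly (write).
#' @export
write_reference_sets <- function(sets, path) {
  jsonlite::write_json(lapply(unclass(sets), as.character), path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference_sets
#' @export
read_reference_sets <- function(path) {
  sets <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(sets, as.character), class = "reference_sets")
}
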