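#' Read and write the package's on-disk formats
#'
#' Cell tables travel as TSV (columns `cell_id, x_um, y_um, sample,
#' condition, compartment, state`), count matrices as a CellRanger-style
#' MatrixMarket triplet (`matrix.mtx`, `features.tsv`, `barcodes.tsv`),
#' simulation ground truth as JSON, and neighborhood memberships as
#' two-column TSV (`neighborhood_id`, `cell_id`).
#'
#' @param cells a cell table data.frame (internal columns `x`, `y` in
#'   micrometres are written as `x_um`, `y_um`).
#' @param path file path (for the triplet, a directory).
#' @name nichetrace-io
NULL

#' @rdname nichetrace-io
#' @export
write_cell_table <- function(cells, path) {
  assert_cells(cells)
  out <- data.frame(cell_id = cells$cell_id, x_um = cells$x, y_um = cells$y,
                    sample = cells$sample, condition = cells$condition,
                    compartment = cells$compartment, state = cells$state,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname nichetrace-io
#' @export
read_cell_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = as.character(x$cell_id), x = x$x_um, y = x$y_um,
                      sample = as.character(x$sample),
                      condition = as.character(x$condition),
                      compartment = as.character(x$compartment),
                      state = as.character(x$state), stringsAsFactors = FALSE)
  assert_cells(cells)
}

#' @rdname nichetrace-io
#' @param counts sparse cells x genes count matrix (`dgCMatrix`), with
#'   rownames = cell ids and colnames = gene symbols.
#' @param genes gene annotation data.frame aligned with `colnames(counts)`.
#' @export
write_counts_mtx <- function(counts, genes, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  # MatrixMarket convention is genes x cells
  Matrix::writeMM(methods::as(Matrix::t(counts), "CsparseMatrix"),
                  file.path(path, "matrix.mtx"))
  utils::write.table(genes, file.path(path, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(rownames(counts), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' @rdname nichetrace-io
#' @export
read_counts_mtx <- function(path) {
  m <- Matrix::readMM(file.path(path, "matrix.mtx"))
  genes <- utils::read.delim(file.path(path, "features.tsv"),
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  counts <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(counts) <- list(barcodes, genes$gene)
  list(counts = counts, genes = genes)
}

#' @rdname nichetrace-io
#' @param truth a `sim_truth` list as returned by [generate_tissue()].
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname nichetrace-io
#' @export
read_neighborhood_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(as.character(x$cell_id), x$neighborhood_id)
}

#' @rdname nichetrace-io
#' @param neighborhoods named list of cell-id vectors.
#' @export
write_neighborhood_tsv <- function(neighborhoods, path) {
  df <- data.frame(
    neighborhood_id = rep(names(neighborhoods), lengths(neighborhoods)),
    cell_id = unlist(neighborhoods, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ligand-receptor table from TSV
#'
#' Expected columns: `ligand`, `receptor` (subunits joined by `;`) and
#' `pathway`. Duplicate (ligand, receptor) rows are dropped.
#'
#' @param path TSV file path.
#' @return data.frame with columns `ligand`, `receptor`, `pathway`.
#' @export
read_lr_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x <- x[!duplicated(x[c("ligand", "receptor")]), , drop = FALSE]
  rownames(x) <- NULL
  x
}
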