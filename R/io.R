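#' Read a 10X-style MatrixMarket triplet into a cell_matrix
#'
#' Reads the CellRanger on-disk layout: a MatrixMarket coordinate file of
#' genes x cells counts plus a genes file and a barcodes file. The genes file
#' may have one or two tab-separated columns (CellRanger v2 writes
#' id + symbol); the first column is used as the gene identifier. The matrix
#' is transposed on read so that cells are in rows.
#'
#' @param matrix_path Path to the `.mtx` file (genes x cells on disk).
#' @param genes_path Path to the genes file, one gene per line.
#' @param barcodes_path Path to the barcodes file, one barcode per line.
#' @return A [cell_matrix()] with `layer == "counts"`.
#' @export
read_mtx_triplet <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) torc_stop("file not found: ", p)
  }
  m <- tryCatch(Matrix::readMM(matrix_path), error = function(e) {
    torc_stop("failed to parse MatrixMarket file ", matrix_path, ": ",
              conditionMessage(e))
  })
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")
  gene_ids <- genes[[1]]
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != length(gene_ids)) {
    torc_stop("matrix has ", nrow(m), " rows but genes file ", genes_path,
              " has ", length(gene_ids), " entries")
  }
  if (ncol(m) != length(barcodes)) {
    torc_stop("matrix has ", ncol(m), " columns but barcodes file ",
              barcodes_path, " has ", length(barcodes), " entries")
  }
  if (anyDuplicated(barcodes)) {
    torc_stop("duplicate barcodes in ", barcodes_path, ": ",
              paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  }
  cell_matrix(as.matrix(Matrix::t(m)), cell_ids = barcodes,
              gene_ids = gene_ids, layer = "counts")
}

#' Write a cell_matrix as a 10X-style MatrixMarket triplet
#'
#' Inverse of [read_mtx_triplet()]: writes the matrix transposed to the
#' on-disk genes x cells orientation.
#'
#' @param m A [cell_matrix()] with `layer == "counts"`.
#' @param matrix_path,genes_path,barcodes_path Output paths.
#' @return Invisibly, `NULL`.
#' @export
write_mtx_triplet <- function(m, matrix_path, genes_path, barcodes_path) {
  stopifnot(inherits(m, "cell_matrix"))
  sp <- methods::as(Matrix::Matrix(t(m$values), sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(sp, matrix_path)
  writeLines(m$gene_ids, genes_path)
  writeLines(m$cell_ids, barcodes_path)
  invisible(NULL)
}

delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a dense delimited expression table
#'
#' Expects a header row of gene names and a first column of cell identifiers.
#' The delimiter is inferred from the extension (tab for `.tsv`/`.txt`,
#' comma otherwise). When a labels file is supplied, labels are joined to
#' cells by identifier -- never by row position -- and a [labeled_dataset()]
#' is returned; every cell in the matrix must then be labeled.
#'
#' @param path Path to the delimited matrix (cells x genes).
#' @param labels_path Optional path to a two-column `cell_id,label` file.
#' @param layer Layer tag for the values (default `"counts"`).
#' @return A [cell_matrix()], or a [labeled_dataset()] when `labels_path`
#'   is given.
#' @export
read_dense <- function(path, labels_path = NULL, layer = "counts") {
  if (!file.exists(path)) torc_stop("file not found: ", path)
  tab <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                           row.names = 1, check.names = FALSE, quote = "\"")
  m <- cell_matrix(as.matrix(tab), cell_ids = rownames(tab),
                   gene_ids = colnames(tab), layer = layer)
  if (is.null(labels_path)) return(m)
  lab <- read_labels(labels_path)
  unknown <- setdiff(lab$cell_id, m$cell_ids)
  if (length(unknown)) {
    torc_stop("labels file contains cells absent from the matrix: ",
              paste(unknown, collapse = ", "))
  }
  unlabeled <- setdiff(m$cell_ids, lab$cell_id)
  if (length(unlabeled)) {
    torc_stop("cells without labels: ", paste(unlabeled, collapse = ", "))
  }
  labels <- lab$label[match(m$cell_ids, lab$cell_id)]
  labeled_dataset(m, labels)
}

#' Read a cell_id,label file
#'
#' @param path Path to a delimited file with columns `cell_id` and `label`.
#' @return A data.frame with character columns `cell_id` and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) torc_stop("file not found: ", path)
  lab <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                           colClasses = "character", quote = "\"")
  if (!all(c("cell_id", "label") %in% names(lab))) {
    torc_stop("labels file must have columns cell_id,label: ", path)
  }
  if (anyDuplicated(lab$cell_id)) {
    torc_stop("duplicate cell_id in labels file: ",
              paste(unique(lab$cell_id[duplicated(lab$cell_id)]),
                    collapse = ", "))
  }
  lab[c("cell_id", "label")]
}

#' Write per-cell labels to a CSV file
#'
#' Writes a two-column file with header `cell_id,label`, one row per cell,
#' preserving input order.
#'
#' @param cell_ids,labels Equal-length character vectors.
#' @param path Output path.
#' @return Invisibly, `NULL`.
#' @export
write_labels <- function(cell_ids, labels, path) {
  if (length(cell_ids) != length(labels)) {
    torc_stop("cell_ids and labels must have equal length")
  }
  df <- data.frame(cell_id = as.character(cell_ids),
                   label = as.character(labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Restrict two matrices to their shared genes
#'
#' Reference and target typically come from different studies with different
#' gene universes; both are restricted to the intersection, in the same
#' order (order of appearance in `a`). Matching is by exact gene identifier.
#'
#' @param a,b Two [cell_matrix()] objects.
#' @return A list with elements `a` and `b`, both restricted to the common
#'   genes in identical column order; cell sets unchanged.
#' @export
intersect_genes <- function(a, b) {
  stopifnot(inherits(a, "cell_matrix"), inherits(b, "cell_matrix"))
  common <- intersect(a$gene_ids, b$gene_ids)
  if (!length(common)) torc_stop("no genes in common between the matrices")
  list(a = subset_genes(a, match(common, a$gene_ids)),
       b = subset_genes(b, match(common, b$gene_ids)))
}
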