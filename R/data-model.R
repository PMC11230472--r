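#' Expression matrix with cell and gene identifiers
#'
#' The common currency of the package: a numeric cells x genes matrix with
#' unique cell and gene identifiers and a `layer` tag recording whether the
#' values are raw counts (`"counts"`) or library-size-normalized
#' log-transformed values (`"lognorm"`).
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   the matrix rownames).
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   the matrix colnames).
#' @param layer Either `"counts"` or `"lognorm"`. Counts must be finite and
#'   non-negative.
#' @return An object of class `cell_matrix`: a list with elements `values`,
#'   `cell_ids`, `gene_ids`, `layer`.
#' @export
#' @examples
#' m <- cell_matrix(matrix(0:5, 2, 3), c("c1", "c2"), c("g1", "g2", "g3"))
#' dim(m$values)
cell_matrix <- function(values, cell_ids = rownames(values),
                        gene_ids = colnames(values), layer = "counts") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids) || is.null(gene_ids)) {
    torc_stop("cell_ids and gene_ids are required (or set as dimnames)")
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids)) {
    torc_stop("nrow(values) [", nrow(values), "] != length(cell_ids) [",
              length(cell_ids), "]")
  }
  if (ncol(values) != length(gene_ids)) {
    torc_stop("ncol(values) [", ncol(values), "] != length(gene_ids) [",
              length(gene_ids), "]")
  }
  if (anyDuplicated(cell_ids)) {
    torc_stop("duplicate cell_ids: ",
              paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    torc_stop("duplicate gene_ids: ",
              paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (!layer %in% c("counts", "lognorm")) {
    torc_stop("layer must be \"counts\" or \"lognorm\", got \"", layer, "\"")
  }
  if (any(!is.finite(values))) torc_stop("values contain non-finite entries")
  if (layer == "counts" && any(values < 0)) {
    torc_stop("counts layer contains negative values")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         layer = layer),
    class = "cell_matrix"
  )
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes, layer \"%s\"\n",
              length(x$cell_ids), length(x$gene_ids), x$layer))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

# row/column subsetting that keeps the invariants intact
subset_cells <- function(m, idx) {
  cell_matrix(m$values[idx, , drop = FALSE], m$cell_ids[idx], m$gene_ids,
              layer = m$layer)
}

subset_genes <- function(m, idx) {
  cell_matrix(m$values[, idx, drop = FALSE], m$cell_ids, m$gene_ids[idx],
              layer = m$layer)
}

#' Expression matrix with per-cell type labels
#'
#' A [cell_matrix()] plus one cell-type label per cell; used for reference
#' (training) data and for evaluation truth.
#'
#' @param matrix A [cell_matrix()].
#' @param labels Character vector, one cell-type label per cell.
#' @param type_names Ordered character vector of the distinct types; defaults
#'   to the sorted unique labels. Every type must occur at least once.
#' @return An object of class `labeled_dataset` with elements `matrix`,
#'   `labels`, `type_names`.
#' @export
labeled_dataset <- function(matrix, labels, type_names = NULL) {
  stopifnot(inherits(matrix, "cell_matrix"))
  labels <- as.character(labels)
  if (length(labels) != length(matrix$cell_ids)) {
    torc_stop("length(labels) [", length(labels), "] != number of cells [",
              length(matrix$cell_ids), "]")
  }
  if (is.null(type_names)) type_names <- sort(unique(labels))
  type_names <- as.character(type_names)
  if (anyDuplicated(type_names)) torc_stop("duplicate type_names")
  missing_types <- setdiff(labels, type_names)
  if (length(missing_types)) {
    torc_stop("labels not in type_names: ",
              paste(missing_types, collapse = ", "))
  }
  absent <- setdiff(type_names, labels)
  if (length(absent)) {
    torc_stop("type_names with zero cells: ", paste(absent, collapse = ", "))
  }
  structure(
    list(matrix = matrix, labels = labels, type_names = type_names),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d cells x %d genes, %d types (%s)\n",
              length(x$matrix$cell_ids), length(x$matrix$gene_ids),
              length(x$type_names),
              paste(utils::head(x$type_names, 5), collapse = ", ")))
  invisible(x)
}

#' Per-cell class-membership probability matrix
#'
#' Validates and tags an n cells x K types row-stochastic matrix as produced
#' by [predict_proba()].
#'
#' @param probs Numeric matrix, one row per cell, one column per type.
#' @param cell_ids,type_names Row and column identifiers; default to the
#'   dimnames of `probs`.
#' @param tol Tolerance on each row sum's deviation from 1 (default `1e-6`).
#' @return `probs` with dimnames set and class `probability_matrix`.
#' @export
probability_matrix <- function(probs, cell_ids = rownames(probs),
                               type_names = colnames(probs), tol = 1e-6) {
  probs <- as.matrix(probs)
  if (is.null(cell_ids) || is.null(type_names)) {
    torc_stop("cell_ids and type_names are required")
  }
  if (length(cell_ids) != nrow(probs) || length(type_names) != ncol(probs)) {
    torc_stop("dimnames do not match probability matrix dimensions")
  }
  if (any(!is.finite(probs)) || any(probs < -tol) || any(probs > 1 + tol)) {
    torc_stop("probabilities must lie in [0, 1]")
  }
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > tol)) {
    torc_stop("probability rows must sum to 1 (max deviation ",
              format(max(abs(rs - 1))), ")")
  }
  dimnames(probs) <- list(as.character(cell_ids), as.character(type_names))
  class(probs) <- c("probability_matrix", class(probs))
  probs
}

#' Cell-type composition vector
#'
#' A probability vector over cell types. The `kind` tag records where the
#' composition came from: the reference's own composition, the target's true
#' (oracle) composition, the composition estimated from first-round
#' predictions, or the equal-weight (uniform) composition.
#'
#' @param proportions Named numeric vector (names are type names) summing
#'   to 1.
#' @param kind One of `"reference"`, `"oracle_target"`, `"estimated_target"`,
#'   `"equal"`.
#' @return A named numeric vector of class `composition` with attribute
#'   `kind`.
#' @export
#' @examples
#' composition(c(B = 0.25, T = 0.75), kind = "reference")
composition <- function(proportions,
                        kind = c("reference", "oracle_target",
                                 "estimated_target", "equal")) {
  kind <- match.arg(kind)
  if (is.null(names(proportions))) torc_stop("proportions must be named")
  proportions <- vapply(proportions, as.numeric, numeric(1))
  if (any(!is.finite(proportions)) || any(proportions < 0) ||
      any(proportions > 1)) {
    torc_stop("proportions must lie in [0, 1]")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    torc_stop("proportions must sum to 1 (got ", format(sum(proportions)), ")")
  }
  structure(proportions, class = "composition", kind = kind)
}

#' Equal-weight composition over a set of types
#'
#' @param type_names Character vector of types.
#' @return A [composition()] with kind `"equal"` giving each type weight 1/K.
#' @export
equal_composition <- function(type_names) {
  k <- length(type_names)
  composition(stats::setNames(rep(1 / k, k), type_names), kind = "equal")
}

#' Observed composition of a labeled dataset
#'
#' @param x A [labeled_dataset()].
#' @param kind Tag for the resulting [composition()]; defaults to
#'   `"reference"`.
#' @return A [composition()] of empirical label frequencies over
#'   `x$type_names`.
#' @export
dataset_composition <- function(x, kind = "reference") {
  stopifnot(inherits(x, "labeled_dataset"))
  counts <- table(factor(x$labels, levels = x$type_names))
  composition(stats::setNames(as.numeric(counts) / length(x$labels),
                              x$type_names),
              kind = kind)
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> kind \"%s\"\n", attr(x, "kind")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
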