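#' Library-size normalization and log transform
#'
#' Scales each cell's counts to a common total (`scale`, default 10,000) and
#' applies a natural log(1 + x) transform -- the standard counts-per-10k
#' "lognorm" used by most scRNA-seq classifiers.
#'
#' @param m A [cell_matrix()] with `layer == "counts"`.
#' @param scale Per-cell count target after scaling.
#' @return A [cell_matrix()] with `layer == "lognorm"`.
#' @export
normalize_log <- function(m, scale = 10000) {
  stopifnot(inherits(m, "cell_matrix"))
  if (m$layer != "counts") torc_stop("normalize_log expects a counts layer")
  totals <- rowSums(m$values)
  zero <- m$cell_ids[totals == 0]
  if (length(zero)) {
    torc_stop("cells with zero total count: ", paste(zero, collapse = ", "))
  }
  out <- log1p(m$values * (scale / totals))
  cell_matrix(out, m$cell_ids, m$gene_ids, layer = "lognorm")
}

#' One-way ANOVA F-test feature selection
#'
#' Ranks genes by a per-gene one-way fixed-effects F statistic across the
#' cell-type groups of the reference (between-group mean square over
#' within-group mean square, with K - 1 and n - K degrees of freedom) and
#' keeps the `n_features` genes with the largest statistic. A gene whose
#' groups are perfectly separated (zero within-group variance, nonzero
#' between-group variance) is a perfect discriminator: its denominator is
#' floored at `1e-12` so it ranks first. A gene that is constant everywhere
#' gets statistic 0. Ties are broken by ascending gene identifier, making
#' the ordering total and the selection deterministic.
#'
#' Selection is computed on the reference only; apply the resulting gene
#' list to the target to avoid leaking target information.
#'
#' @param ref A [labeled_dataset()] with `layer == "lognorm"`, at least two
#'   types, each with at least two cells.
#' @param n_features Number of genes to keep.
#' @return A list of class `feature_selection` with `selected_gene_ids`
#'   (descending F order), `f_statistics` (named, one per candidate gene),
#'   and `n_features`.
#' @export
f_test_select <- function(ref, n_features) {
  stopifnot(inherits(ref, "labeled_dataset"))
  if (ref$matrix$layer != "lognorm") {
    torc_stop("f_test_select expects lognorm values; run normalize_log first")
  }
  if (!is_count(n_features)) torc_stop("n_features must be a positive integer")
  x <- ref$matrix$values
  if (n_features > ncol(x)) {
    torc_stop("n_features (", n_features, ") exceeds gene count (", ncol(x), ")")
  }
  g <- factor(ref$labels, levels = ref$type_names)
  if (nlevels(g) < 2) torc_stop("need at least 2 cell types")
  n_per <- table(g)
  small <- names(n_per)[n_per < 2]
  if (length(small)) {
    torc_stop("types with fewer than 2 cells: ", paste(small, collapse = ", "))
  }
  n <- nrow(x)
  k <- nlevels(g)
  # two-pass: center by grand means, then group sums of centered values
  xc <- sweep(x, 2, colMeans(x))
  sst <- colSums(xc^2)
  group_sums <- rowsum(xc, g)                      # k x genes
  ssb <- colSums(group_sums^2 / as.numeric(n_per))
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msb <= 0, 0, msb / pmax(msw, 1e-12))
  names(f) <- ref$matrix$gene_ids
  ord <- order(-f, names(f))
  structure(
    list(selected_gene_ids = names(f)[ord][seq_len(n_features)],
         f_statistics = f,
         n_features = as.integer(n_features)),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d of %d genes; top: %s\n",
              x$n_features, length(x$f_statistics),
              paste(utils::head(x$selected_gene_ids, 5), collapse = ", ")))
  invisible(x)
}

#' Restrict a matrix to selected genes
#'
#' Subsets a [cell_matrix()] to a gene list (a [f_test_select()] result or a
#' character vector), in the list's order; errors if any gene is missing.
#'
#' @param m A [cell_matrix()].
#' @param selected_gene_ids A `feature_selection` or character vector.
#' @return A [cell_matrix()] with columns reordered to the selection.
#' @export
apply_features <- function(m, selected_gene_ids) {
  if (inherits(selected_gene_ids, "feature_selection")) {
    selected_gene_ids <- selected_gene_ids$selected_gene_ids
  }
  idx <- match(selected_gene_ids, m$gene_ids)
  if (anyNA(idx)) {
    torc_stop("genes missing from matrix: ",
              paste(selected_gene_ids[is.na(idx)], collapse = ", "))
  }
  subset_genes(m, idx)
}
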