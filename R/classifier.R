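#' Classifier configuration
#'
#' Describes the supervised backend used to label target cells. The default
#' is a multi-layer perceptron (ReLU hidden layers, softmax output, Adam,
#' early stopping on a stratified 10% validation split) -- the baseline that
#' benchmark studies of supervised cell-typing found strongest when paired
#' with F-test feature selection. A `"centroid"` backend (nearest shrunken-
#' free centroid with softmax over negative distances) is included mainly to
#' demonstrate that any backend honoring the fit/predict contract can drive
#' the pipeline.
#'
#' @param backend `"mlp"` or `"centroid"`, or a custom backend registered
#'   via a list (see Details).
#' @param hidden_sizes Integer vector of hidden-layer widths (MLP only).
#' @param max_epochs,learning_rate,batch_size Optimizer settings (MLP only).
#' @param early_stopping Stop when validation loss stops improving.
#' @param standardize Per-gene standardization (zero mean, unit variance)
#'   fitted on the training data and applied to both training and target
#'   values.
#' @param seed Integer seed; fitting is deterministic given data and seed.
#'
#' @details A custom backend is a list with elements `fit(x, y, spec)`
#'   returning an opaque state and `predict_proba(state, x)` returning an
#'   n x K probability matrix with columns in `levels(y)` order. Pass it as
#'   `backend`; everything else in the pipeline is backend-agnostic.
#'
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(backend = "mlp",
                            hidden_sizes = 100L,
                            max_epochs = 200L,
                            learning_rate = 1e-3,
                            batch_size = 64L,
                            early_stopping = TRUE,
                            standardize = TRUE,
                            seed = 1L) {
  if (is.character(backend)) {
    backend <- match.arg(backend, c("mlp", "centroid"))
  } else if (!is.list(backend) ||
             !all(c("fit", "predict_proba") %in% names(backend))) {
    torc_stop("backend must be \"mlp\", \"centroid\", or a list with fit ",
              "and predict_proba functions")
  }
  hidden_sizes <- as.integer(hidden_sizes)
  if (!length(hidden_sizes) || any(hidden_sizes < 1)) {
    torc_stop("hidden_sizes must be a nonempty vector of positive integers")
  }
  if (!is_count(max_epochs)) torc_stop("max_epochs must be >= 1")
  if (!is_number(learning_rate) || learning_rate <= 0) {
    torc_stop("learning_rate must be positive")
  }
  if (!is_count(batch_size)) torc_stop("batch_size must be >= 1")
  if (!is_flag(early_stopping) || !is_flag(standardize)) {
    torc_stop("early_stopping and standardize must be single logicals")
  }
  structure(
    list(backend = backend, hidden_sizes = hidden_sizes,
         max_epochs = as.integer(max_epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), early_stopping = early_stopping,
         standardize = standardize, seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

backend_fns <- function(backend) {
  if (is.list(backend)) return(backend)
  switch(backend,
    mlp = list(
      fit = function(x, y, spec) {
        mlp_train(x, as.integer(y), nlevels(y),
                  hidden_sizes = spec$hidden_sizes,
                  learning_rate = spec$learning_rate,
                  max_epochs = spec$max_epochs,
                  batch_size = spec$batch_size,
                  early_stopping = spec$early_stopping)
      },
      predict_proba = function(state, x) mlp_predict_proba(state, x)
    ),
    centroid = list(
      fit = function(x, y, spec) {
        list(centroids = rowsum(x, y) / as.vector(table(y)))
      },
      predict_proba = function(state, x) {
        d2 <- outer(rowSums(x^2), rowSums(state$centroids^2), "+") -
          2 * x %*% t(state$centroids)
        z <- -d2
        z <- z - apply(z, 1, max)
        ez <- exp(z)
        ez / rowSums(ez)
      }
    ),
    torc_stop("unknown backend: ", backend)
  )
}

#' Train a classifier on a labeled reference
#'
#' Cells are sorted by cell identifier before fitting so results do not
#' depend on input row order; all randomness (weight initialization,
#' minibatch order, validation split) flows from `spec$seed`, so refitting
#' with the same data and seed reproduces the model exactly. Type names are
#' stored in sorted order and fix the probability-matrix column order.
#'
#' @param ref A [labeled_dataset()], normally lognorm values restricted to
#'   the selected features.
#' @param spec A [classifier_spec()].
#' @return A list of class `fitted_classifier` with `spec`, `type_names`,
#'   `selected_gene_ids`, standardization parameters, and the opaque
#'   backend state.
#' @export
fit_classifier <- function(ref, spec = classifier_spec()) {
  stopifnot(inherits(ref, "labeled_dataset"), inherits(spec, "classifier_spec"))
  if (length(ref$type_names) < 2) {
    torc_stop("reference must contain at least 2 cell types")
  }
  ord <- order(ref$matrix$cell_ids)
  x <- ref$matrix$values[ord, , drop = FALSE]
  if (any(!is.finite(x))) torc_stop("non-finite values in training data")
  type_names <- sort(ref$type_names)
  y <- factor(ref$labels[ord], levels = type_names)

  center <- scale_sd <- NULL
  if (spec$standardize) {
    center <- colMeans(x)
    scale_sd <- pmax(apply(x, 2, stats::sd), 1e-8)
    x <- sweep(sweep(x, 2, center), 2, scale_sd, "/")
  }
  fns <- backend_fns(spec$backend)
  state <- with_seed(spec$seed, fns$fit(x, y, spec))
  structure(
    list(spec = spec, type_names = type_names,
         selected_gene_ids = ref$matrix$gene_ids,
         center = center, scale_sd = scale_sd, state = state),
    class = "fitted_classifier"
  )
}

#' Predict class-membership probabilities for target cells
#'
#' @param clf A [fitted_classifier()][fit_classifier].
#' @param target A [cell_matrix()] containing (at least) the classifier's
#'   selected genes; columns are matched by gene identifier.
#' @return A [probability_matrix()] over `clf$type_names`, rows in the
#'   target's cell order.
#' @export
predict_proba <- function(clf, target) {
  stopifnot(inherits(clf, "fitted_classifier"), inherits(target, "cell_matrix"))
  target <- apply_features(target, clf$selected_gene_ids)
  x <- target$values
  if (!is.null(clf$center)) {
    x <- sweep(sweep(x, 2, clf$center), 2, clf$scale_sd, "/")
  }
  fns <- backend_fns(clf$spec$backend)
  p <- fns$predict_proba(clf$state, x)
  p <- p / rowSums(p)
  probability_matrix(p, cell_ids = target$cell_ids,
                     type_names = clf$type_names)
}

#' Hard labels from a probability matrix
#'
#' Per-cell argmax over types; exact ties go to the earlier column in
#' `type_names` order.
#'
#' @param p A [probability_matrix()].
#' @return Character vector of labels named by cell identifier.
#' @export
predict_labels <- function(p) {
  idx <- apply(unclass(p), 1, which.max)   # which.max takes the first maximum
  stats::setNames(colnames(p)[idx], rownames(p))
}
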