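#' TORC configuration
#'
#' Algorithmic knobs of the two-round target-oriented reference
#' construction.
#'
#' @param expand_pool Add high-confidence target cells (with their
#'   first-round pseudo-labels) to the reference pool before resampling.
#'   Recommended when reference and target come from different studies,
#'   where domain shift is expected.
#' @param entropy_quantile Confidence gate: within each group, cells with
#'   prediction entropy at or below this empirical quantile are deemed
#'   high-confidence. In (0, 1]; default 0.25 (per-type gating keeps the
#'   pseudo-label error of the gated cells low while admitting enough
#'   target cells for the expansion to matter).
#' @param per_type_gating Gate within each predicted type (default), so
#'   abundant easy types cannot crowd out rare types; `FALSE` uses one
#'   global quantile.
#' @param composition_mode `"hard"` (default) estimates the target
#'   composition from argmax label counts; `"soft"` uses probability-column
#'   means.
#' @param reference_size Cell count of the constructed reference:
#'   `"match_original"` (default) keeps the original reference's size so
#'   only composition and cell provenance change, or a positive integer.
#' @param sample_with_replacement_fallback When a type's pool is smaller
#'   than its allotted count, sample that type with replacement (default);
#'   otherwise cap at the pool size with a warning.
#' @param min_cells_per_type Floor on the constructed reference's per-type
#'   count, applied only to types with positive estimated proportion;
#'   prevents degenerate near-empty classes. Floors are funded by removing
#'   cells from the most abundant types.
#' @param seed Root seed; child seeds for the two classifier fits and the
#'   resampling are derived from it deterministically.
#' @return A list of class `torc_config`.
#' @export
torc_config <- function(expand_pool = TRUE,
                        entropy_quantile = 0.25,
                        per_type_gating = TRUE,
                        composition_mode = c("hard", "soft"),
                        reference_size = "match_original",
                        sample_with_replacement_fallback = TRUE,
                        min_cells_per_type = 10L,
                        seed = 1L) {
  composition_mode <- match.arg(composition_mode)
  if (!is_number(entropy_quantile) || entropy_quantile <= 0 ||
      entropy_quantile > 1) {
    torc_stop("entropy_quantile must be in (0, 1]")
  }
  if (!identical(reference_size, "match_original") &&
      !is_count(reference_size)) {
    torc_stop("reference_size must be \"match_original\" or a positive integer")
  }
  if (!is.numeric(min_cells_per_type) || min_cells_per_type < 0) {
    torc_stop("min_cells_per_type must be a nonnegative integer")
  }
  if (!is_flag(expand_pool) || !is_flag(per_type_gating) ||
      !is_flag(sample_with_replacement_fallback)) {
    torc_stop("expand_pool, per_type_gating and ",
              "sample_with_replacement_fallback must be single logicals")
  }
  structure(
    list(expand_pool = expand_pool,
         entropy_quantile = entropy_quantile,
         per_type_gating = per_type_gating,
         composition_mode = composition_mode,
         reference_size = reference_size,
         sample_with_replacement_fallback = sample_with_replacement_fallback,
         min_cells_per_type = as.integer(min_cells_per_type),
         seed = as.integer(seed)),
    class = "torc_config"
  )
}

#' Per-cell prediction entropy
#'
#' Shannon entropy of each cell's predicted class-probability row,
#' \eqn{H_i = -\sum_k p_{ik} \log p_{ik}} with natural log and
#' \eqn{0 \log 0 := 0}. Low entropy marks a high-confidence prediction;
#' entropy lies in \eqn{[0, \log K]}.
#'
#' @param p A [probability_matrix()].
#' @return Named numeric vector, one entropy per cell.
#' @export
entropy <- function(p) {
  p <- unclass(p)
  h <- -rowSums(ifelse(p > 0, p * log(p), 0))
  stats::setNames(pmax(h, 0), rownames(p))
}

#' Estimate target cell-type composition from predictions
#'
#' @param p A [probability_matrix()] for the target cells.
#' @param mode `"hard"`: fraction of cells whose argmax is each type;
#'   `"soft"`: column means of the probabilities.
#' @return A [composition()] with kind `"estimated_target"`.
#' @export
estimate_composition <- function(p, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  types <- colnames(p)
  if (mode == "hard") {
    labels <- predict_labels(p)
    prop <- as.numeric(table(factor(labels, levels = types))) / nrow(p)
  } else {
    prop <- colMeans(unclass(p))
    prop <- prop / sum(prop)
  }
  composition(stats::setNames(prop, types), kind = "estimated_target")
}

#' Select high-confidence target cells by entropy quantile
#'
#' The confidence threshold is an empirical entropy quantile (inclusive
#' lower quantile, the "inverted CDF" definition): a cell qualifies when its
#' entropy is less than or equal to its group's
#' `entropy_quantile`-th quantile. With per-type gating (default) the
#' quantile is computed within each predicted type; otherwise globally.
#'
#' @param e Named numeric entropy vector, as from [entropy()].
#' @param labels Character vector of first-round predicted labels, aligned
#'   with `e`.
#' @param cfg A [torc_config()].
#' @return Character vector of selected cell identifiers.
#' @export
select_confident <- function(e, labels, cfg = torc_config()) {
  if (length(e) != length(labels)) {
    torc_stop("entropies and labels must be aligned")
  }
  ids <- names(e)
  if (is.null(ids)) torc_stop("entropy vector must be named by cell id")
  q <- cfg$entropy_quantile
  if (cfg$per_type_gating) {
    keep <- unlist(lapply(split(seq_along(e), labels), function(idx) {
      thr <- stats::quantile(e[idx], q, type = 1, names = FALSE)
      idx[e[idx] <= thr]
    }), use.names = FALSE)
    ids[sort(keep)]
  } else {
    thr <- stats::quantile(e, q, type = 1, names = FALSE)
    ids[e <= thr]
  }
}

#' Expand the reference pool with pseudo-labeled target cells
#'
#' Selected target cells join the reference pool carrying their first-round
#' predicted labels. Pool cell identifiers are prefixed with their origin
#' (`"ref:"` / `"target:"`) so the two sources can never collide, and the
#' provenance of every pool cell is recoverable from its identifier.
#'
#' @param ref A [labeled_dataset()] (counts layer recommended, so the
#'   constructed reference can be renormalized cleanly).
#' @param target A [cell_matrix()] on the same genes as `ref`.
#' @param confident_ids Target cell identifiers to add (subset of
#'   `target$cell_ids`).
#' @param first_labels Named character vector of first-round predicted
#'   labels covering `confident_ids`.
#' @return A [labeled_dataset()] pool; equal to `ref` (with prefixed ids)
#'   when `confident_ids` is empty.
#' @export
expand_pool <- function(ref, target, confident_ids, first_labels) {
  stopifnot(inherits(ref, "labeled_dataset"), inherits(target, "cell_matrix"))
  if (!identical(ref$matrix$gene_ids, target$gene_ids)) {
    torc_stop("reference and target must share an identical gene order")
  }
  bad <- setdiff(confident_ids, target$cell_ids)
  if (length(bad)) {
    torc_stop("confident_ids not in target: ", paste(bad, collapse = ", "))
  }
  ref_ids <- paste0("ref:", ref$matrix$cell_ids)
  if (!length(confident_ids)) {
    m <- cell_matrix(ref$matrix$values, ref_ids, ref$matrix$gene_ids,
                     layer = ref$matrix$layer)
    return(labeled_dataset(m, ref$labels, ref$type_names))
  }
  add_labels <- first_labels[confident_ids]
  if (anyNA(add_labels)) {
    torc_stop("first_labels missing for some confident cells")
  }
  unknown <- setdiff(add_labels, ref$type_names)
  if (length(unknown)) {
    torc_stop("pseudo-labels outside reference types: ",
              paste(unknown, collapse = ", "))
  }
  tgt <- subset_cells(target, match(confident_ids, target$cell_ids))
  values <- rbind(ref$matrix$values, tgt$values)
  ids <- c(ref_ids, paste0("target:", confident_ids))
  m <- cell_matrix(values, ids, ref$matrix$gene_ids, layer = ref$matrix$layer)
  labeled_dataset(m, c(ref$labels, unname(add_labels)), ref$type_names)
}

#' Largest-remainder (Hamilton) apportionment
#'
#' Converts fractional expected counts `size * proportions` into integers
#' that sum exactly to `size`: each type gets the floor of its expectation,
#' and the remaining cells go to the types with the largest fractional
#' remainders, ties broken by type order. Each resulting count deviates
#' from its expectation by less than 1.
#'
#' @param proportions Numeric vector summing to 1.
#' @param size Total count to apportion.
#' @return Integer vector summing to `size`, named like `proportions`.
#' @export
apportion_counts <- function(proportions, size) {
  expected <- proportions * size
  counts <- floor(expected)
  remainder <- size - sum(counts)
  if (remainder > 0) {
    frac <- expected - counts
    extra <- order(-frac, seq_along(frac))[seq_len(remainder)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

# per-type counts with the min_cells_per_type floor applied to types with
# positive proportion; floors are funded from the largest counts
resample_counts <- function(comp, size, min_cells) {
  counts <- apportion_counts(as.numeric(comp), size)
  names(counts) <- names(comp)
  pos <- as.numeric(comp) > 0
  if (min_cells > 0) {
    if (size < sum(pos) * min_cells) {
      torc_stop("size (", size, ") too small for ", sum(pos),
                " types at min_cells_per_type = ", min_cells)
    }
    repeat {
      deficit_types <- which(pos & counts < min_cells)
      if (!length(deficit_types)) break
      need <- sum(min_cells - counts[deficit_types])
      counts[deficit_types] <- min_cells
      # take the needed cells from the most abundant types, one at a time
      for (i in seq_len(need)) {
        donors <- which(counts > min_cells | (!pos & counts > 0))
        donor <- donors[which.max(counts[donors])]
        counts[donor] <- counts[donor] - 1L
      }
    }
  }
  counts
}

#' Resample a reference from the pool to match a composition
#'
#' Draws a constructed reference of `size` cells from the (possibly
#' expanded) pool with per-type counts given by largest-remainder
#' apportionment of `size * comp`, so the constructed composition matches
#' `comp` to within one cell per type. Within each type, cells are sampled
#' without replacement when the pool suffices and with replacement otherwise
#' (if the fallback is enabled; duplicated draws get a `#k` suffix on their
#' identifier). Types with zero proportion contribute no cells.
#'
#' @param pool A [labeled_dataset()] (the reference pool).
#' @param comp A [composition()] over (a subset of) the pool's types.
#' @param size Number of cells in the constructed reference.
#' @param cfg A [torc_config()] (controls the replacement fallback and the
#'   per-type floor).
#' @param rng_seed Seed making the draw deterministic.
#' @return A [labeled_dataset()] with exactly `size` cells.
#' @export
resample_reference <- function(pool, comp, size, cfg = torc_config(),
                               rng_seed = cfg$seed) {
  stopifnot(inherits(pool, "labeled_dataset"))
  comp_names <- names(comp)
  missing_types <- setdiff(comp_names[as.numeric(comp) > 0], pool$type_names)
  if (length(missing_types)) {
    torc_stop("types with positive proportion absent from pool: ",
              paste(missing_types, collapse = ", "))
  }
  counts <- resample_counts(comp, size, cfg$min_cells_per_type)
  by_type <- split(seq_along(pool$labels), pool$labels)
  picked <- with_seed(rng_seed, {
    unlist(lapply(comp_names[counts > 0], function(ty) {
      avail <- by_type[[ty]]
      n_take <- counts[[ty]]
      if (is.null(avail)) {
        torc_stop("no pool cells of type ", ty)
      }
      if (n_take <= length(avail)) {
        sample(avail, n_take)
      } else if (cfg$sample_with_replacement_fallback) {
        sample(avail, n_take, replace = TRUE)
      } else {
        warning("pool has only ", length(avail), " cells of type ", ty,
                " for a request of ", n_take, "; capping")
        avail
      }
    }), use.names = FALSE)
  })
  ids <- pool$matrix$cell_ids[picked]
  dup <- duplicated(ids)
  if (any(dup)) {
    ids[dup] <- paste0(ids[dup], "#", stats::ave(seq_along(ids), ids,
                                                 FUN = seq_along)[dup])
  }
  m <- cell_matrix(pool$matrix$values[picked, , drop = FALSE], ids,
                   pool$matrix$gene_ids, layer = pool$matrix$layer)
  keep_types <- pool$type_names[pool$type_names %in% pool$labels[picked]]
  labeled_dataset(m, pool$labels[picked], keep_types)
}

#' Construct a reference from a pool under a user-supplied composition
#'
#' The same operation as [resample_reference()], exposed for strategy
#' comparisons: supply the target's true (oracle) composition, the
#' equal-weight composition, or any other composition of interest.
#'
#' @inheritParams resample_reference
#' @param seed Seed making the draw deterministic.
#' @return A [labeled_dataset()].
#' @export
construct_reference <- function(pool, comp, size, cfg = torc_config(),
                                seed = cfg$seed) {
  resample_reference(pool, comp, size, cfg = cfg, rng_seed = seed)
}

#' Run the full two-round TORC pipeline
#'
#' Executes: gene intersection, normalization, F-test feature selection on
#' the reference, first-round fit and target prediction, per-cell entropy,
#' target-composition estimation, optional entropy-gated pool expansion,
#' composition-matched resampling of the pool, feature re-selection (when
#' `reselect_features`), second-round fit, and final target prediction. All
#' randomness flows from `cfg$seed` through three derived child seeds
#' (round-1 fit, resampling, round-2 fit).
#'
#' @param ref A [labeled_dataset()] with raw counts.
#' @param target A [cell_matrix()] with raw counts; gene universe
#'   intersectable with the reference's.
#' @param spec A [classifier_spec()].
#' @param cfg A [torc_config()].
#' @param n_features Number of genes kept by F-test selection.
#' @param normalize_scale Per-cell total for count normalization.
#' @param reselect_features Recompute feature selection on the constructed
#'   reference before the second-round fit (default `TRUE`).
#' @return A list of class `torc_result` with `final_labels`,
#'   `first_round_labels`, `estimated_composition`, `entropies`,
#'   `pool_added_cell_ids`, `constructed_reference_composition`, and `seed`.
#' @export
run_torc <- function(ref, target, spec = classifier_spec(),
                     cfg = torc_config(), n_features = 1000,
                     normalize_scale = 10000, reselect_features = TRUE) {
  stopifnot(inherits(ref, "labeled_dataset"), inherits(target, "cell_matrix"))
  seeds <- derive_seeds(cfg$seed, 3L)
  n_features <- min(n_features, length(intersect(ref$matrix$gene_ids,
                                                 target$gene_ids)))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      torc_stop("[", name, "] ", conditionMessage(e))
    })
  }

  shared <- stage("intersect_genes", intersect_genes(ref$matrix, target))
  ref_counts <- labeled_dataset(shared$a, ref$labels, ref$type_names)
  target_counts <- shared$b

  ref_norm <- stage("normalize", labeled_dataset(
    normalize_log(shared$a, normalize_scale), ref$labels, ref$type_names))
  target_norm <- stage("normalize", normalize_log(target_counts,
                                                  normalize_scale))

  sel <- stage("feature_selection", f_test_select(ref_norm, n_features))
  ref_feat <- labeled_dataset(apply_features(ref_norm$matrix,
                                             sel$selected_gene_ids),
                              ref$labels, ref$type_names)

  spec1 <- spec
  spec1$seed <- seeds[1]
  clf1 <- stage("fit_round1", fit_classifier(ref_feat, spec1))
  p1 <- stage("predict_round1", predict_proba(clf1, target_norm))
  first_labels <- predict_labels(p1)
  ent <- entropy(p1)
  comp_hat <- estimate_composition(p1, cfg$composition_mode)

  added <- character(0)
  if (cfg$expand_pool) {
    added <- select_confident(ent, first_labels, cfg)
  }
  pool <- stage("expand_pool",
                expand_pool(ref_counts, target_counts, added, first_labels))

  size <- if (identical(cfg$reference_size, "match_original")) {
    length(ref$labels)
  } else {
    cfg$reference_size
  }
  constructed <- stage("resample_reference",
                       resample_reference(pool, comp_hat, size, cfg,
                                          rng_seed = seeds[2]))

  constructed_norm <- stage("normalize", labeled_dataset(
    normalize_log(constructed$matrix, normalize_scale),
    constructed$labels, constructed$type_names))
  sel2 <- if (reselect_features) {
    stage("feature_selection",
          f_test_select(constructed_norm,
                        min(n_features, length(constructed_norm$matrix$gene_ids))))
  } else {
    sel
  }
  constructed_feat <- labeled_dataset(
    apply_features(constructed_norm$matrix, sel2$selected_gene_ids),
    constructed$labels, constructed$type_names)

  spec2 <- spec
  spec2$seed <- seeds[3]
  clf2 <- stage("fit_round2", fit_classifier(constructed_feat, spec2))
  p2 <- stage("predict_round2", predict_proba(clf2, target_norm))

  structure(
    list(final_labels = predict_labels(p2),
         first_round_labels = first_labels,
         estimated_composition = comp_hat,
         entropies = ent,
         pool_added_cell_ids = added,
         constructed_reference_composition =
           dataset_composition(constructed, kind = "estimated_target"),
         seed = cfg$seed),
    class = "torc_result"
  )
}

#' @export
print.torc_result <- function(x, ...) {
  cat(sprintf(paste0("<torc_result> %d target cells; %d pool-added cells; ",
                     "estimated composition:\n"),
              length(x$final_labels), length(x$pool_added_cell_ids)))
  print(round(stats::setNames(as.numeric(x$estimated_composition),
                              names(x$estimated_composition)), 3))
  invisible(x)
}
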