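#' Score predicted labels against truth
#'
#' Accuracy is the fraction of exactly matching label strings
#' (case-sensitive; silent fuzzy matching hides errors). The confusion
#' matrix is built over the union of truth and predicted type sets, rows =
#' truth, columns = predicted.
#'
#' @param truth,predicted Equal-length character vectors aligned by cell.
#' @return A list of class `eval_report` with `accuracy`, `per_type_recall`,
#'   `confusion`, and `n_cells`.
#' @export
score_labels <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    torc_stop("truth and predicted must have equal length")
  }
  types <- sort(union(truth, predicted))
  confusion <- table(factor(truth, levels = types),
                     factor(predicted, levels = types))
  confusion <- matrix(as.integer(confusion), nrow = length(types),
                      dimnames = list(truth = types, predicted = types))
  n <- length(truth)
  acc <- sum(diag(confusion)) / n
  row_tot <- rowSums(confusion)
  recall <- ifelse(row_tot > 0, diag(confusion) / row_tot, NA_real_)
  structure(
    list(accuracy = acc,
         per_type_recall = stats::setNames(recall, types),
         confusion = confusion,
         n_cells = n),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f over %d cells\n",
              x$accuracy, x$n_cells))
  invisible(x)
}

#' Compare reference-construction strategies
#'
#' Reruns the classification under several reference-construction strategies
#' with shared seeds (paired across strategies) and tabulates accuracy:
#'
#' * `"original"` -- train on the reference as given (composition P^R);
#' * `"oracle"` -- resample the pool to the target's true composition P^T;
#' * `"estimated"` -- resample to the composition estimated from the
#'   first-round predictions (the TORC strategy, P-hat^T);
#' * `"equal"` -- resample to the equal-weight composition P-bar.
#'
#' All resampling strategies share the original reference (plus pool
#' expansion, if `cfg$expand_pool`) and the first-round classifier within
#' each seed; only the composition differs, so differences isolate the
#' composition effect.
#'
#' @param ref A [labeled_dataset()] (counts).
#' @param target_truth A [labeled_dataset()] (counts) whose labels are the
#'   evaluation truth.
#' @param strategies Subset of `c("original", "oracle", "estimated",
#'   "equal")`.
#' @param n_seeds Number of paired replicate seeds.
#' @param spec A [classifier_spec()].
#' @param cfg A [torc_config()].
#' @param n_features,normalize_scale Passed to the pipeline.
#' @param master_seed Root seed generating the per-replicate seeds.
#' @return A list with `tidy` (strategy, seed, accuracy) and `summary`
#'   (strategy, mean, sd, n_seeds) data frames. With `n_seeds = 1` the sd
#'   column is 0 by convention and flagged in a `note` attribute.
#' @export
compare_strategies <- function(ref, target_truth,
                               strategies = c("original", "oracle",
                                              "estimated", "equal"),
                               n_seeds = 20, spec = classifier_spec(),
                               cfg = torc_config(), n_features = 1000,
                               normalize_scale = 10000, master_seed = 1L) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (!is_count(n_seeds)) torc_stop("n_seeds must be >= 1")
  target <- target_truth$matrix
  truth <- target_truth$labels
  seeds <- derive_seeds(master_seed, n_seeds)

  n_features <- min(n_features, length(intersect(ref$matrix$gene_ids,
                                                 target$gene_ids)))
  shared <- intersect_genes(ref$matrix, target)
  ref_counts <- labeled_dataset(shared$a, ref$labels, ref$type_names)
  target_counts <- shared$b
  ref_norm <- labeled_dataset(normalize_log(shared$a, normalize_scale),
                              ref$labels, ref$type_names)
  target_norm <- normalize_log(target_counts, normalize_scale)
  sel <- f_test_select(ref_norm, n_features)
  ref_feat <- labeled_dataset(apply_features(ref_norm$matrix,
                                             sel$selected_gene_ids),
                              ref$labels, ref$type_names)

  oracle_comp <- composition(
    stats::setNames(as.numeric(table(factor(truth,
                                            levels = ref$type_names))) /
                      length(truth), ref$type_names),
    kind = "oracle_target")
  equal_comp <- equal_composition(ref$type_names)
  size <- if (identical(cfg$reference_size, "match_original")) {
    length(ref$labels)
  } else {
    cfg$reference_size
  }

  refit_score <- function(constructed, fit_seed) {
    cons_norm <- labeled_dataset(
      normalize_log(constructed$matrix, normalize_scale),
      constructed$labels, constructed$type_names)
    sel2 <- f_test_select(cons_norm,
                          min(n_features, length(cons_norm$matrix$gene_ids)))
    cons_feat <- labeled_dataset(
      apply_features(cons_norm$matrix, sel2$selected_gene_ids),
      constructed$labels, constructed$type_names)
    spec2 <- spec
    spec2$seed <- fit_seed
    clf <- fit_classifier(cons_feat, spec2)
    score_labels(truth, predict_labels(predict_proba(clf, target_norm)))$accuracy
  }

  rows <- list()
  for (i in seq_len(n_seeds)) {
    sub_seeds <- derive_seeds(seeds[i], 4L)
    spec1 <- spec
    spec1$seed <- sub_seeds[1]
    clf1 <- fit_classifier(ref_feat, spec1)
    p1 <- predict_proba(clf1, target_norm)
    first_labels <- predict_labels(p1)

    pool <- ref_counts
    if (cfg$expand_pool) {
      ent <- entropy(p1)
      added <- select_confident(ent, first_labels, cfg)
      pool <- expand_pool(ref_counts, target_counts, added, first_labels)
    } else {
      pool <- expand_pool(ref_counts, target_counts, character(0),
                          first_labels)
    }

    for (strat in strategies) {
      acc <- switch(strat,
        original = score_labels(truth, first_labels)$accuracy,
        oracle = refit_score(
          construct_reference(pool, oracle_comp, size, cfg,
                              seed = sub_seeds[2]), sub_seeds[3]),
        estimated = refit_score(
          construct_reference(pool, estimate_composition(
            p1, cfg$composition_mode), size, cfg,
            seed = sub_seeds[2]), sub_seeds[3]),
        equal = refit_score(
          construct_reference(pool, equal_comp, size, cfg,
                              seed = sub_seeds[2]), sub_seeds[3])
      )
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = strat, seed = seeds[i], accuracy = acc)
    }
  }
  tidy <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(tidy, tidy$strategy), function(d) {
    data.frame(strategy = d$strategy[1], mean = mean(d$accuracy),
               sd = if (nrow(d) > 1) stats::sd(d$accuracy) else 0,
               n_seeds = nrow(d))
  }))
  summary <- summary[match(strategies, summary$strategy), ]
  rownames(summary) <- NULL
  out <- list(tidy = tidy, summary = summary)
  if (n_seeds == 1) attr(out, "note") <- "sd is 0 by convention (n_seeds = 1)"
  out
}
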