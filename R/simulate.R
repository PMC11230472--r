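#' Simulation specification for reference/target pairs
#'
#' Describes a synthetic scRNA-seq reference/target pair with known truth:
#' negative-binomial counts with cell-type-specific mean profiles, optional
#' confusable type pairs, arbitrary reference and target compositions, and
#' an optional multiplicative gene-wise batch (domain-shift) effect applied
#' to the target only.
#'
#' Each type owns a disjoint block of `n_marker_genes_per_type` marker
#' genes whose log-mean is raised by `marker_logfc` over the baseline. A
#' confusable pair shares marker effects: each member also expresses its
#' partner's markers at `separation_scale` times the full effect, so
#' `separation_scale = 0` leaves the pair fully separated and
#' `separation_scale = 1` makes the two profiles identical. (This mimics
#' closely related subtypes, such as cytotoxic versus naive cytotoxic
#' T cells, which differ only in part of their signature.)
#'
#' Per-type cell counts come from deterministic largest-remainder
#' apportionment of the compositions, so the realized compositions are
#' exact, not multinomial draws.
#'
#' @param K Number of cell types (named "type1" ... "typeK").
#' @param n_genes Total genes.
#' @param n_marker_genes_per_type Marker block size per type; requires
#'   `K * n_marker_genes_per_type <= n_genes`.
#' @param marker_logfc Natural-log fold change of marker means over
#'   baseline.
#' @param confusable_pairs List of `list(pair = c(i, j), separation_scale =
#'   s)` entries with `s` in `[0, 1]` as described above.
#' @param ref_composition,target_composition [composition()] vectors over
#'   the K types (defaults: equal).
#' @param n_ref,n_target Cell counts.
#' @param batch_effect_sd Standard deviation of the per-gene log-normal
#'   batch factor applied to target means only; 0 disables it.
#' @param baseline_mean Baseline NB mean per gene.
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param seed Seed; the draw is fully reproducible.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(K = 4, n_genes = 500, n_marker_genes_per_type = 20,
                     marker_logfc = 2, confusable_pairs = list(),
                     ref_composition = NULL, target_composition = NULL,
                     n_ref = 2000, n_target = 2000, batch_effect_sd = 0,
                     baseline_mean = 0.5, dispersion = 2, seed = 1L) {
  if (!is_count(K) || K < 2) torc_stop("K must be an integer >= 2")
  if (!is_count(n_genes)) torc_stop("n_genes must be a positive integer")
  if (!is_count(n_marker_genes_per_type)) {
    torc_stop("n_marker_genes_per_type must be a positive integer")
  }
  if (K * n_marker_genes_per_type > n_genes) {
    torc_stop("K * n_marker_genes_per_type (", K * n_marker_genes_per_type,
              ") exceeds n_genes (", n_genes, ")")
  }
  types <- paste0("type", seq_len(K))
  if (is.null(ref_composition)) ref_composition <- equal_composition(types)
  if (is.null(target_composition)) {
    target_composition <- equal_composition(types)
  }
  for (comp in list(ref_composition, target_composition)) {
    if (!identical(names(comp), types)) {
      torc_stop("compositions must be named over ", paste(types,
                                                          collapse = ", "))
    }
  }
  for (cp in confusable_pairs) {
    if (!all(c("pair", "separation_scale") %in% names(cp)) ||
        length(cp$pair) != 2 || any(!cp$pair %in% seq_len(K)) ||
        cp$separation_scale < 0 || cp$separation_scale > 1) {
      torc_stop("each confusable pair needs pair = c(i, j) within 1..K and ",
                "separation_scale in [0, 1]")
    }
  }
  if (!is_number(batch_effect_sd) || batch_effect_sd < 0) {
    torc_stop("batch_effect_sd must be >= 0")
  }
  if (!is_number(baseline_mean) || baseline_mean <= 0) {
    torc_stop("baseline_mean must be > 0")
  }
  if (!is_number(dispersion) || dispersion <= 0) {
    torc_stop("dispersion must be > 0")
  }
  structure(
    list(K = as.integer(K), n_genes = as.integer(n_genes),
         n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
         marker_logfc = marker_logfc, confusable_pairs = confusable_pairs,
         ref_composition = ref_composition,
         target_composition = target_composition,
         n_ref = as.integer(n_ref), n_target = as.integer(n_target),
         batch_effect_sd = batch_effect_sd, baseline_mean = baseline_mean,
         dispersion = dispersion, seed = as.integer(seed),
         type_names = types),
    class = "sim_spec"
  )
}

# K x n_genes matrix of log means implied by the spec
sim_log_means <- function(spec) {
  mu <- matrix(log(spec$baseline_mean), spec$K, spec$n_genes,
               dimnames = list(spec$type_names, NULL))
  marker_idx <- lapply(seq_len(spec$K), function(k) {
    (k - 1L) * spec$n_marker_genes_per_type +
      seq_len(spec$n_marker_genes_per_type)
  })
  for (k in seq_len(spec$K)) {
    mu[k, marker_idx[[k]]] <- mu[k, marker_idx[[k]]] + spec$marker_logfc
  }
  for (cp in spec$confusable_pairs) {
    a <- cp$pair[1]
    b <- cp$pair[2]
    s <- cp$separation_scale
    mu[a, marker_idx[[b]]] <- log(spec$baseline_mean) + s * spec$marker_logfc
    mu[b, marker_idx[[a]]] <- log(spec$baseline_mean) + s * spec$marker_logfc
  }
  attr(mu, "marker_idx") <- marker_idx
  mu
}

sim_draw_counts <- function(mu_rows, dispersion) {
  n <- nrow(mu_rows)
  g <- ncol(mu_rows)
  counts <- matrix(stats::rnbinom(n * g, mu = exp(as.vector(mu_rows)),
                                  size = dispersion), n, g)
  counts
}

#' Simulate a reference/target pair with known truth
#'
#' Draws the reference, then the gene-wise batch factors, then the target,
#' all from `spec$seed`; per-type cell counts are deterministic, so changing
#' only `batch_effect_sd` changes only target expression values, never any
#' label.
#'
#' @param spec A [sim_spec()].
#' @return A list with elements `ref` and `target`, both
#'   [labeled_dataset()]s with raw counts (the target's labels are the
#'   held-out truth).
#' @export
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  mu <- sim_log_means(spec)
  gene_ids <- sprintf("gene%04d", seq_len(spec$n_genes))

  ref_counts_per_type <- apportion_counts(as.numeric(spec$ref_composition),
                                          spec$n_ref)
  tgt_counts_per_type <- apportion_counts(as.numeric(spec$target_composition),
                                          spec$n_target)
  ref_labels <- rep(spec$type_names, ref_counts_per_type)
  tgt_labels <- rep(spec$type_names, tgt_counts_per_type)

  with_seed(spec$seed, {
    ref_mu <- mu[match(ref_labels, spec$type_names), , drop = FALSE]
    ref_values <- sim_draw_counts(ref_mu, spec$dispersion)
    batch <- stats::rnorm(spec$n_genes, 0, spec$batch_effect_sd)
    tgt_mu <- mu[match(tgt_labels, spec$type_names), , drop = FALSE]
    tgt_mu <- sweep(tgt_mu, 2, batch, "+")
    tgt_values <- sim_draw_counts(tgt_mu, spec$dispersion)

    ref <- labeled_dataset(
      cell_matrix(ref_values, sprintf("ref_%05d", seq_len(spec$n_ref)),
                  gene_ids),
      ref_labels, spec$type_names[spec$type_names %in% ref_labels])
    target <- labeled_dataset(
      cell_matrix(tgt_values, sprintf("tgt_%05d", seq_len(spec$n_target)),
                  gene_ids),
      tgt_labels, spec$type_names[spec$type_names %in% tgt_labels])
    list(ref = ref, target = target)
  })
}

#' Composition-reversal scenario
#'
#' Returns a copy of `base` whose reference composition gives the chosen
#' type pair odds `odds_ref` (e.g. 4, meaning 4:1) and whose target
#' composition gives odds `odds_target` (e.g. 0.25, i.e. 1:4), while the
#' pair's combined mass and every other type's proportion are preserved
#' exactly. This recreates the classic stress test where the relative
#' abundance of two hard-to-distinguish subtypes is reversed between
#' reference and target.
#'
#' @param base A [sim_spec()].
#' @param pair Integer vector `c(i, j)` of the two types.
#' @param odds_ref,odds_target Positive odds of type `i` to type `j` in the
#'   reference and target compositions.
#' @return A modified [sim_spec()].
#' @export
reversal_scenario <- function(base, pair, odds_ref, odds_target) {
  stopifnot(inherits(base, "sim_spec"))
  if (length(pair) != 2 || any(!pair %in% seq_len(base$K))) {
    torc_stop("pair must name two types in 1..K")
  }
  if (odds_ref <= 0 || odds_target <= 0) torc_stop("odds must be positive")
  set_odds <- function(comp, odds, kind) {
    p <- as.numeric(comp)
    m <- p[pair[1]] + p[pair[2]]
    if (m <= 0) torc_stop("the pair has zero combined mass")
    p[pair[1]] <- m * odds / (1 + odds)
    p[pair[2]] <- m / (1 + odds)
    composition(stats::setNames(p, names(comp)), kind = kind)
  }
  base$ref_composition <- set_odds(base$ref_composition, odds_ref,
                                   "reference")
  base$target_composition <- set_odds(base$target_composition, odds_target,
                                      "oracle_target")
  base
}
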