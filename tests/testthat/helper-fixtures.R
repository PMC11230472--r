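# Shared fixtures, all generated in code.

# small counts matrix with deterministic entries
tiny_counts <- function(n_cells = 4, n_genes = 3, seed = 42) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  vals <- withr_seed(matrix(rpois(n_cells * n_genes, 5), n_cells, n_genes))
  cell_matrix(vals, sprintf("c%d", seq_len(n_cells)),
              sprintf("g%d", seq_len(n_genes)))
}

# two well-separated Gaussian clouds in lognorm space, as a labeled_dataset
separable_dataset <- function(n_per = 50, d = 10, gap = 6, seed = 1) {
  set.seed(seed)
  xa <- matrix(rnorm(n_per * d, 0, 1), n_per, d)
  xb <- matrix(rnorm(n_per * d, 0, 1), n_per, d)
  xb[, 1:3] <- xb[, 1:3] + gap
  x <- abs(rbind(xa, xb))
  m <- cell_matrix(x, sprintf("c%03d", seq_len(2 * n_per)),
                   sprintf("g%d", seq_len(d)), layer = "lognorm")
  labeled_dataset(m, rep(c("A", "B"), each = n_per))
}

# fast classifier settings for pipeline-level tests
fast_mlp <- function(seed = 1) {
  classifier_spec(hidden_sizes = 16L, max_epochs = 40L, batch_size = 64L,
                  seed = seed)
}

# a small but nontrivial simulated pair
small_sim_pair <- function(seed = 3, ...) {
  simulate_pair(sim_spec(K = 3, n_genes = 120, n_marker_genes_per_type = 10,
                         marker_logfc = 2, n_ref = 240, n_target = 240,
                         seed = seed, ...))
}

# independent brute-force one-way ANOVA for a single gene
anova_f_oracle <- function(values, groups) {
  fit <- stats::anova(stats::lm(values ~ factor(groups)))
  fit[["F value"]][1]
}
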