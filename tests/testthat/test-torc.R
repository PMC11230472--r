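test_that("entropy matches closed forms and the brute-force formula", {
  p <- probability_matrix(
    rbind(c(1, 0, 0, 0),
          c(0.25, 0.25, 0.25, 0.25),
          c(0.5, 0.5, 0, 0)),
    c("c1", "c2", "c3"), c("A", "B", "C", "D"))
  h <- entropy(p)
  expect_equal(unname(h), c(0, log(4), log(2)))

  set.seed(13)
  for (k in c(2, 5, 9)) {
    raw <- matrix(rexp(40 * k), 40, k)
    raw <- raw / rowSums(raw)
    pm <- probability_matrix(raw, sprintf("c%d", 1:40),
                             sprintf("T%d", 1:k))
    brute <- apply(raw, 1, function(r) {
      s <- 0
      for (v in r) if (v > 0) s <- s - v * log(v)
      s
    })
    expect_equal(unname(entropy(pm)), brute, tolerance = 1e-12)
    expect_true(all(entropy(pm) >= 0 & entropy(pm) <= log(k) + 1e-12))
  }
})

test_that("estimate_composition counts labels (hard) or averages mass (soft)", {
  p <- probability_matrix(
    rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.3, 0.7), c(0.1, 0.9)),
    sprintf("c%d", 1:4), c("A", "B"))
  expect_equal(as.numeric(estimate_composition(p, "hard")), c(0.5, 0.5))
  expect_equal(as.numeric(estimate_composition(p, "soft")),
               c(mean(c(0.9, 0.8, 0.3, 0.1)), mean(c(0.1, 0.2, 0.7, 0.9))))
  expect_identical(attr(estimate_composition(p, "hard"), "kind"),
                   "estimated_target")

  # hard and soft agree in the one-hot limit
  onehot <- probability_matrix(rbind(c(1, 0), c(1, 0), c(0, 1)),
                               sprintf("c%d", 1:3), c("A", "B"))
  expect_equal(as.numeric(estimate_composition(onehot, "hard")),
               as.numeric(estimate_composition(onehot, "soft")))

  # hard mode times n is an integer vector summing to n
  set.seed(3)
  raw <- matrix(rexp(60), 20, 3)
  raw <- raw / rowSums(raw)
  pm <- probability_matrix(raw, sprintf("c%d", 1:20), c("A", "B", "C"))
  counts <- as.numeric(estimate_composition(pm, "hard")) * 20
  expect_equal(counts, round(counts))
  expect_equal(sum(counts), 20)
})

test_that("select_confident applies the inclusive lower entropy quantile", {
  e <- setNames(seq(0.1, 1.0, by = 0.1), sprintf("c%d", 1:10))
  labs <- rep("A", 10)
  cfg <- torc_config(entropy_quantile = 0.10)
  expect_identical(select_confident(e, labs, cfg), "c1")

  expect_setequal(
    select_confident(e, labs, torc_config(entropy_quantile = 1)),
    names(e))
  all_equal <- setNames(rep(0.3, 6), sprintf("c%d", 1:6))
  expect_setequal(select_confident(all_equal, rep("A", 6), cfg),
                  names(all_equal))

  # per-type gating takes each type's own quantile; global gating does not
  e2 <- setNames(c(0.1, 0.2, 0.8, 0.9), sprintf("c%d", 1:4))
  labs2 <- c("A", "A", "B", "B")
  per_type <- select_confident(e2, labs2, torc_config(entropy_quantile = 0.5))
  expect_setequal(per_type, c("c1", "c3"))
  global <- select_confident(e2, labs2,
                             torc_config(entropy_quantile = 0.5,
                                         per_type_gating = FALSE))
  expect_setequal(global, c("c1", "c2"))
})

test_that("expand_pool adds pseudo-labeled target cells with provenance", {
  pair <- small_sim_pair()
  ref <- pair$ref
  target <- pair$target$matrix
  first_labels <- setNames(pair$target$labels, target$cell_ids)

  empty <- expand_pool(ref, target, character(0), first_labels)
  expect_equal(length(empty$labels), length(ref$labels))
  expect_identical(empty$labels, ref$labels)

  picked <- target$cell_ids[1:5]
  pool <- expand_pool(ref, target, picked, first_labels)
  expect_equal(length(pool$labels), length(ref$labels) + 5)
  expect_identical(pool$type_names, ref$type_names)
  added_idx <- match(paste0("target:", picked), pool$matrix$cell_ids)
  expect_false(anyNA(added_idx))
  expect_identical(pool$labels[added_idx], unname(first_labels[picked]))

  expect_error(expand_pool(ref, target, "nope", first_labels), "nope")
})

test_that("largest-remainder apportionment is exact and deterministic", {
  expect_equal(unname(apportion_counts(c(1, 0), 50)), c(50L, 0L))
  expect_equal(unname(apportion_counts(c(0.5, 0.5), 51)), c(26L, 25L))
  expect_equal(unname(apportion_counts(c(0.7, 0.3), 1000)), c(700L, 300L))

  set.seed(21)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    p <- rexp(k)
    p <- p / sum(p)
    size <- sample(10:500, 1)
    counts <- apportion_counts(p, size)
    expect_equal(sum(counts), size)
    expect_true(all(abs(counts - size * p) < 1))
  }
})

test_that("resample_reference honours composition, size and determinism", {
  pair <- small_sim_pair()
  pool <- expand_pool(pair$ref, pair$target$matrix, character(0),
                      setNames(pair$target$labels,
                               pair$target$matrix$cell_ids))
  cfg <- torc_config(min_cells_per_type = 0L)

  comp <- composition(c(type1 = 0.7, type2 = 0.3, type3 = 0),
                      kind = "oracle_target")
  out <- resample_reference(pool, comp, 200, cfg, rng_seed = 8)
  tab <- table(factor(out$labels, levels = c("type1", "type2", "type3")))
  expect_equal(as.numeric(tab), c(140, 60, 0))

  out2 <- resample_reference(pool, comp, 200, cfg, rng_seed = 8)
  expect_identical(out$matrix$cell_ids, out2$matrix$cell_ids)

  # pool's own composition at pool size without replacement: a permutation
  own <- dataset_composition(pool)
  perm <- resample_reference(pool, own, length(pool$labels), cfg,
                             rng_seed = 3)
  expect_setequal(perm$matrix$cell_ids, pool$matrix$cell_ids)

  bad <- composition(c(type1 = 0.5, type2 = 0.25, type9 = 0.25),
                     kind = "oracle_target")
  expect_error(resample_reference(pool, bad, 100, cfg), "type9")
})

test_that("scarce types fall back to replacement sampling", {
  pair <- small_sim_pair()
  pool <- expand_pool(pair$ref, pair$target$matrix, character(0),
                      setNames(pair$target$labels,
                               pair$target$matrix$cell_ids))
  n1 <- sum(pool$labels == "type1")
  comp <- composition(c(type1 = 1, type2 = 0, type3 = 0),
                      kind = "oracle_target")
  big <- resample_reference(pool, comp, n1 + 50,
                            torc_config(min_cells_per_type = 0L),
                            rng_seed = 5)
  expect_equal(length(big$labels), n1 + 50)
  expect_true(all(big$labels == "type1"))

  capped <- suppressWarnings(resample_reference(
    pool, comp, n1 + 50,
    torc_config(min_cells_per_type = 0L,
                sample_with_replacement_fallback = FALSE),
    rng_seed = 5))
  expect_equal(length(capped$labels), n1)
})

test_that("min_cells_per_type floors are funded from abundant types", {
  pair <- small_sim_pair()
  pool <- expand_pool(pair$ref, pair$target$matrix, character(0),
                      setNames(pair$target$labels,
                               pair$target$matrix$cell_ids))
  comp <- composition(c(type1 = 0.98, type2 = 0.01, type3 = 0.01),
                      kind = "oracle_target")
  cfg <- torc_config(min_cells_per_type = 10L)
  out <- resample_reference(pool, comp, 100, cfg, rng_seed = 2)
  tab <- table(factor(out$labels, levels = pool$type_names))
  expect_equal(sum(tab), 100)
  expect_true(all(tab[c("type2", "type3")] >= 10))
  expect_error(resample_reference(pool, comp, 25, cfg), "too small")
})

test_that("the full pipeline is deterministic and returns coherent output", {
  pair <- small_sim_pair()
  run <- function() {
    run_torc(pair$ref, pair$target$matrix, spec = fast_mlp(),
             cfg = torc_config(seed = 77), n_features = 40)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$final_labels, r2$final_labels)
  expect_identical(r1$estimated_composition, r2$estimated_composition)
  expect_identical(r1$pool_added_cell_ids, r2$pool_added_cell_ids)

  expect_equal(sum(as.numeric(r1$estimated_composition)), 1)
  expect_true(all(r1$pool_added_cell_ids %in% pair$target$matrix$cell_ids))
  expect_setequal(names(r1$final_labels), pair$target$matrix$cell_ids)
  expect_length(r1$entropies, 240)
})

test_that("pipeline errors carry the failing stage name", {
  pair <- small_sim_pair()
  other <- cell_matrix(pair$target$matrix$values,
                       pair$target$matrix$cell_ids,
                       paste0("x_", pair$target$matrix$gene_ids))
  expect_error(run_torc(pair$ref, other, spec = fast_mlp()),
               "intersect_genes")
})
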