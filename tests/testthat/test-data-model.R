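test_that("cell_matrix enforces its invariants", {
  vals <- matrix(1:6, 2, 3)
  expect_s3_class(cell_matrix(vals, c("c1", "c2"), c("g1", "g2", "g3")),
                  "cell_matrix")
  expect_error(cell_matrix(vals, c("c1", "c1"), c("g1", "g2", "g3")),
               "duplicate cell_ids")
  expect_error(cell_matrix(vals, c("c1", "c2"), c("g1", "g2")),
               "ncol")
  expect_error(cell_matrix(-vals, c("c1", "c2"), c("g1", "g2", "g3")),
               "negative")
  expect_error(cell_matrix(vals * NA, c("c1", "c2"), c("g1", "g2", "g3")),
               "non-finite")
})

test_that("labeled_dataset ties labels to cells and types", {
  m <- tiny_counts()
  ds <- labeled_dataset(m, c("A", "A", "B", "B"))
  expect_identical(ds$type_names, c("A", "B"))
  expect_error(labeled_dataset(m, c("A", "A", "B")), "number of cells")
  expect_error(labeled_dataset(m, c("A", "A", "B", "B"),
                               type_names = c("A", "B", "C")),
               "zero cells")
  expect_error(labeled_dataset(m, c("A", "A", "B", "Z"),
                               type_names = c("A", "B")),
               "Z")
})

test_that("MTX triplet read transposes the on-disk genes x cells layout", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "3 2 2"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("g1\tGENE1", "g2\tGENE2", "g3\tGENE3"),
             file.path(dir, "genes.tsv"))
  writeLines(c("bc1", "bc2"), file.path(dir, "barcodes.tsv"))
  m <- read_mtx_triplet(file.path(dir, "matrix.mtx"),
                        file.path(dir, "genes.tsv"),
                        file.path(dir, "barcodes.tsv"))
  expect_identical(m$gene_ids, c("g1", "g2", "g3"))
  expect_identical(m$cell_ids, c("bc1", "bc2"))
  expect_equal(unname(m$values),
               matrix(c(5, 0, 0, 0, 0, 2), 2, 3, byrow = TRUE))
})

test_that("MTX reader rejects malformed or inconsistent triplets", {
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "matrix.mtx")
  genes <- file.path(dir, "genes.tsv")
  bcs <- file.path(dir, "barcodes.tsv")
  writeLines(character(0), mtx)
  writeLines(c("g1", "g2", "g3"), genes)
  writeLines(c("bc1", "bc2"), bcs)
  expect_error(read_mtx_triplet(mtx, genes, bcs), "parse")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 1", "1 1 5"), mtx)
  writeLines(c("g1", "g2"), genes)
  expect_error(read_mtx_triplet(mtx, genes, bcs), "genes")
  writeLines(c("g1", "g2", "g3"), genes)
  writeLines(c("bc1", "bc1"), bcs)
  expect_error(read_mtx_triplet(mtx, genes, bcs), "duplicate barcodes")
})

test_that("MTX triplet write/read round-trips a random sparse matrix", {
  set.seed(11)
  dense <- matrix(0, 100, 50)
  nz <- sample(length(dense), 400)
  dense[nz] <- rpois(400, 3) + 1
  m <- cell_matrix(dense, sprintf("c%03d", 1:100), sprintf("g%02d", 1:50))
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("m.mtx", "g.tsv", "b.tsv"))
  write_mtx_triplet(m, paths[1], paths[2], paths[3])
  back <- read_mtx_triplet(paths[1], paths[2], paths[3])
  expect_equal(back$values, m$values)
  expect_identical(back$cell_ids, m$cell_ids)
  expect_identical(back$gene_ids, m$gene_ids)
})

test_that("dense reader joins labels by cell id, not row order", {
  dir <- withr::local_tempdir()
  mat_path <- file.path(dir, "expr.csv")
  writeLines(c("cell,g1,g2", "c1,1,2", "c2,3,4"), mat_path)
  lab_path <- file.path(dir, "labels.csv")

  writeLines(c("cell_id,label", "c1,A", "c2,B"), lab_path)
  ds <- read_dense(mat_path, lab_path)
  expect_s3_class(ds, "labeled_dataset")
  expect_identical(ds$type_names, c("A", "B"))
  expect_identical(ds$labels, c("A", "B"))

  writeLines(c("cell_id,label", "c2,B", "c1,A"), lab_path)
  ds_shuffled <- read_dense(mat_path, lab_path)
  expect_identical(ds_shuffled, ds)

  writeLines(c("cell_id,label", "c1,A", "c9,B"), lab_path)
  expect_error(read_dense(mat_path, lab_path), "c9")
  writeLines(c("cell_id,label", "c1,A"), lab_path)
  expect_error(read_dense(mat_path, lab_path), "without labels")
})

test_that("intersect_genes restricts both matrices to shared genes", {
  a <- cell_matrix(matrix(1, 2, 3), c("c1", "c2"), c("g1", "g2", "g3"))
  b <- cell_matrix(matrix(2, 2, 3), c("d1", "d2"), c("g2", "g3", "g4"))
  out <- intersect_genes(a, b)
  expect_identical(out$a$gene_ids, c("g2", "g3"))
  expect_identical(out$b$gene_ids, c("g2", "g3"))
  expect_identical(out$a$cell_ids, a$cell_ids)

  # idempotent, and symmetric in the gene set produced
  again <- intersect_genes(out$a, out$b)
  expect_identical(again$a, out$a)
  rev <- intersect_genes(b, a)
  expect_setequal(rev$a$gene_ids, out$a$gene_ids)

  # identical gene sets: outputs equal inputs up to column order
  same <- intersect_genes(a, a)
  expect_identical(same$a, a)

  d <- cell_matrix(matrix(3, 2, 2), c("e1", "e2"), c("h1", "h2"))
  expect_error(intersect_genes(a, d), "no genes in common")
})

test_that("write_labels emits a header plus one row per cell and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels("c1", "B cell", path)
  expect_length(readLines(path), 2)

  write_labels(character(0), character(0), path)
  expect_identical(readLines(path), "cell_id,label")

  ids <- sprintf("c%d", 1:5)
  labs <- c("A", "B", "A", "C", "B")
  write_labels(ids, labs, path)
  back <- read_labels(path)
  expect_identical(back$cell_id, ids)
  expect_identical(back$label, labs)

  expect_error(write_labels(ids, labs[1:3], path), "equal length")
})

test_that("probability_matrix and composition validate their contracts", {
  p <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE)
  pm <- probability_matrix(p, c("c1", "c2"), c("A", "B"))
  expect_s3_class(pm, "probability_matrix")
  expect_error(probability_matrix(p * 2, c("c1", "c2"), c("A", "B")),
               "sum to 1|\\[0, 1\\]")
  expect_error(composition(c(A = 0.5, B = 0.4)), "sum to 1")
  expect_error(composition(c(0.5, 0.5)), "named")
  expect_equal(as.numeric(equal_composition(c("A", "B", "C", "D"))),
               rep(0.25, 4))
})
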