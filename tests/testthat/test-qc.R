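test_that("MTX triplet reading matches what was written", {
  cm <- random_cm(5, 3, seed = 1)
  # force a known nnz pattern
  expect_identical(dim(cm$counts), c(5L, 3L))
  dir <- withr::local_tempdir()
  write_counts(cm, dir)
  back <- read_counts(dir)
  expect_identical(as.matrix(back$counts), as.matrix(cm$counts))
  expect_identical(back$gene_ids, cm$gene_ids)
  expect_identical(back$cell_ids, cm$cell_ids)
})

test_that("duplicate gene symbols are de-duplicated with .1 suffixes", {
  dir <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(1:6, 2, 3), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(c("ACTA2\tACTA2", "ACTA2\tACTA2"), file.path(dir, "features.tsv"))
  writeLines(c("b1", "b2", "b3"), file.path(dir, "barcodes.tsv"))
  cm <- read_counts(dir)
  expect_identical(cm$gene_ids, c("ACTA2", "ACTA2.1"))
})

test_that("malformed inputs raise format errors", {
  dir <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(1:6, 2, 3), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "features.tsv"))  # 3 != 2
  writeLines(c("b1", "b2", "b3"), file.path(dir, "barcodes.tsv"))
  expect_error(read_counts(dir), "do not match")

  csv <- file.path(dir, "bad.csv")
  writeLines(c("gene,c1,c2", "g1,1.5,2"), csv)
  expect_error(read_counts(csv), "non-integer")
})

test_that("dense CSV input is read genes x cells", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "counts.csv")
  writeLines(c("gene,c1,c2", "g1,0,2", "g2,3,0"), csv)
  cm <- read_counts(csv)
  expect_identical(dim(cm$counts), c(2L, 2L))
  expect_identical(as.numeric(cm$counts["g2", "c1"]), 3)
})

test_that("gene filter retains exactly the brute-force survivor set", {
  cfg <- qc_config()
  cm <- random_cm(200, 100, mu = 0.05, seed = 7)
  kept <- filter_genes(cm, cfg)
  oracle <- cm$gene_ids[
    apply(as.matrix(cm$counts), 1, function(r) sum(r > 0)) >= 3]
  expect_identical(kept$gene_ids, oracle)
  expect_identical(kept$cell_ids, cm$cell_ids)

  # boundary: detected in exactly 3 cells is retained, 2 is removed
  m <- matrix(0, 2, 5)
  m[1, 1:3] <- 1
  m[2, 1:2] <- 1
  cm2 <- count_matrix(Matrix::Matrix(m, sparse = TRUE), c("keep3", "drop2"),
                      paste0("c", 1:5))
  expect_identical(filter_genes(cm2, cfg)$gene_ids, "keep3")
})

test_that("cell filter applies the closed [min,max] gene and <=5% mito rules", {
  cfg <- qc_config(min_genes_per_cell = 3, max_genes_per_cell = 5,
                   max_mito_pct = 5)
  # cells with 2..6 detected genes
  m <- matrix(0, 7, 5)
  for (j in 1:5) m[seq_len(j + 1), j] <- 1
  cm <- count_matrix(Matrix::Matrix(m, sparse = TRUE), paste0("g", 1:7),
                     paste0("c", 1:5))
  kept <- filter_cells(cm, cfg)
  expect_identical(kept$cell_ids, c("c2", "c3", "c4"))  # 3,4,5 genes

  # mito boundary: exactly 5.0% retained, above excluded
  m2 <- rbind(`MT-1` = c(5, 6), G1 = c(95, 94))
  cm2 <- count_matrix(Matrix::Matrix(m2, sparse = TRUE), rownames(m2),
                      c("at5", "above5"))
  cfg2 <- qc_config(min_genes_per_cell = 1, max_genes_per_cell = 10)
  expect_identical(filter_cells(cm2, cfg2)$cell_ids, "at5")
})

test_that("cell filter matches a brute-force per-cell oracle on random data", {
  cfg <- qc_config(min_genes_per_cell = 20, max_genes_per_cell = 60,
                   max_mito_pct = 5)
  cm <- random_cm(80, 120, mu = 0.8, seed = 3)
  gene_ids <- cm$gene_ids
  gene_ids[1:4] <- paste0("MT-", 1:4)
  cm <- count_matrix(cm$counts, gene_ids, cm$cell_ids)
  kept <- filter_cells(cm, cfg)
  dense <- as.matrix(cm$counts)
  oracle <- cm$cell_ids[vapply(seq_len(ncol(dense)), function(j) {
    ng <- sum(dense[, j] > 0)
    pm <- 100 * sum(dense[1:4, j]) / sum(dense[, j])
    ng >= 20 && ng <= 60 && pm <= 5
  }, logical(1))]
  expect_identical(kept$cell_ids, oracle)
})

test_that("filters are idempotent and do not mutate their input", {
  cm <- random_cm(100, 60, mu = 0.3, seed = 11)
  snapshot <- as.matrix(cm$counts)
  cfg <- qc_config(min_genes_per_cell = 5, max_genes_per_cell = 90)
  f1 <- filter_cells(filter_genes(cm, cfg), cfg)
  f2 <- filter_cells(filter_genes(f1, cfg), cfg)
  expect_identical(as.matrix(f1$counts), as.matrix(f2$counts))
  expect_identical(as.matrix(cm$counts), snapshot)
})

test_that("doublet scoring is seeded, bounded, and flags the exact quantile", {
  sim <- generate_two_species(small_gen(seed = 12, doublet_rate = 0.08))
  cm <- sim$species_a
  cfg <- qc_config(doublet_expected_rate = 0.05)
  d1 <- detect_doublets(cm, cfg, seed = 3)
  d2 <- detect_doublets(cm, cfg, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(d1$doublet_score >= 0 & d1$doublet_score <= 1))
  expect_identical(sum(d1$doublet_flag),
                   as.integer(round(0.05 * ncol(cm$counts))))
  expect_error(detect_doublets(random_cm(20, 10), cfg), "at least")
})

test_that("doublet score separates planted doublets (AUROC > 0.8)", {
  skip_if_not_installed("pROC")
  sim <- generate_two_species(small_gen(seed = 13, doublet_rate = 0.08))
  cm <- sim$species_a
  dd <- detect_doublets(cm, qc_config(doublet_expected_rate = 0.08), seed = 1)
  truth <- sim$truth$doublet_flags[dd$cell_id]
  auc <- as.numeric(pROC::auc(pROC::roc(truth, dd$doublet_score,
                                        quiet = TRUE)))
  expect_gt(auc, 0.8)
})

test_that("run_qc reports attrition and drops flagged doublets", {
  sim <- generate_two_species(small_gen(seed = 14))
  res <- run_qc(sim$species_a, qc_config(min_genes_per_cell = 10), seed = 2)
  expect_true(all(c("n_genes", "pct_mito", "doublet_score", "kept") %in%
                    names(res$report)))
  expect_identical(sum(res$report$kept), ncol(res$filtered$counts))
  expect_lt(ncol(res$filtered$counts), ncol(sim$species_a$counts))
})
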