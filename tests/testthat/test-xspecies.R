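write_omap <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  path
}

test_that("ortholog maps resolve to one-to-one pairs", {
  dir <- withr::local_tempdir()
  p <- write_omap(data.frame(a = c("A1", "A2"), b = c("b1", "b2")),
                  file.path(dir, "m1.tsv"))
  om <- suppressMessages(load_orthologs(p))
  expect_identical(nrow(om), 2L)

  # A1 mapped to two partners: dropped entirely
  p2 <- write_omap(data.frame(a = c("A1", "A1", "A2"),
                              b = c("b1", "b2", "b3")),
                   file.path(dir, "m2.tsv"))
  om2 <- suppressMessages(load_orthologs(p2))
  expect_identical(om2$gene_a, "A2")

  # pairs with genes absent from a dataset are dropped
  om3 <- suppressMessages(load_orthologs(p, genes_a = c("A1"),
                                         genes_b = c("b1", "b2")))
  expect_identical(om3$gene_a, "A1")

  writeLines("onlyonecolumn", file.path(dir, "bad.tsv"))
  expect_error(load_orthologs(file.path(dir, "bad.tsv")), "2 columns")
})

test_that("a generated bijective map is retained in full", {
  sim <- generate_two_species(small_gen(seed = 41))
  dir <- withr::local_tempdir()
  p <- write_omap(sim$truth$ortholog_map, file.path(dir, "omap.tsv"))
  om <- suppressMessages(load_orthologs(p, genes_a = sim$species_a$gene_ids,
                                        genes_b = sim$species_b$gene_ids))
  expect_identical(nrow(om), nrow(sim$truth$ortholog_map))
})

mk_table <- function(type, genes) {
  n <- length(genes)
  data.frame(cluster = type, gene = genes, U_statistic = 0,
             p_value = 0, p_adj_BH = 0, avg_log2FC = seq(n, 1), pct_in = 1,
             pct_out = 0, stringsAsFactors = FALSE)
}

test_that("shared marker set: identity, disjoint and planted-marker cases", {
  omap <- data.frame(gene_a = paste0("A", 1:100), gene_b = paste0("b", 1:100))
  ta <- mk_table("SMC", paste0("A", 1:10))
  tb <- mk_table("SMC", paste0("b", 1:10))
  sh <- shared_marker_set(ta, tb, omap, n = 10)
  expect_identical(sh$per_type$SMC, paste0("A", 1:10))

  tb2 <- mk_table("SMC", paste0("b", 51:60))
  expect_length(shared_marker_set(ta, tb2, omap, n = 10)$genes, 0)

  expect_error(shared_marker_set(ta, mk_table("EC", "b1"), omap),
               "type_pairing")
})

test_that("planted ortholog markers survive the cross-species top-n intersection", {
  cfg <- generator_config(cells_per_type_per_condition =
                            c(control = 100, aneurysm = 100),
                          n_marker_genes_per_type = 10, doublet_rate = 0,
                          seed = 42)
  sim <- generate_two_species(cfg)
  nms <- lapply(list(A = sim$species_a, B = sim$species_b), lognormalize)
  labs <- lapply(nms, function(nm) sim$truth$cell_labels[nm$cell_ids])
  mks <- lapply(names(nms), function(sp) all_markers(nms[[sp]], labs[[sp]]))
  names(mks) <- names(nms)
  omap <- sim$truth$ortholog_map
  sh <- shared_marker_set(mks$A, mks$B, omap, n = 50)
  for (ty in names(sim$truth$homology)) {
    planted <- sim$truth$planted_markers[[ty]]
    expect_gte(length(intersect(sh$per_type[[ty]], planted)), 8)
  }
})

test_that("pseudobulk equals a naive group-by mean and is linear", {
  cm <- random_cm(20, 30, mu = 2, seed = 43)
  nm <- lognormalize(cm)
  lab <- setNames(rep(c("x", "y", "z"), each = 10), cm$cell_ids)
  pb <- pseudobulk(nm, lab, nm$gene_ids[1:7])
  dense <- as.matrix(nm$values)
  for (cl in c("x", "y", "z"))
    expect_equal(unname(pb[cl, ]),
                 unname(rowMeans(dense[1:7, lab == cl])), tolerance = 1e-12)

  # one-cell cluster equals that cell; equal halves average
  lab1 <- setNames(c("solo", rep("rest", 29)), cm$cell_ids)
  pb1 <- pseudobulk(nm, lab1, nm$gene_ids[1:3])
  expect_equal(unname(pb1["solo", ]), unname(dense[1:3, 1]))
})

test_that("correspondence on a duplicated pseudobulk pairs namesakes at 1", {
  set.seed(44)
  pb <- matrix(rnorm(5 * 40), 5, 40,
               dimnames = list(paste0("t", 1:5), paste0("g", 1:40)))
  res <- correspondence(pb, pb)
  expect_identical(res$pairing$cluster_b, res$pairing$cluster_a)
  expect_equal(res$pairing$similarity, rep(1, 5), tolerance = 1e-12)
  # namesakes merge before any cross-type merge: the first 5 merges each
  # join an A-row with its B twin at height ~0
  h <- res$linkage
  early <- h$merge[h$height < 1e-9, , drop = FALSE]
  expect_identical(nrow(early), 5L)
  expect_true(all(early < 0))  # leaf-leaf merges
  expect_true(all(diff(h$height) >= -1e-12))
})

test_that("correspondence handles the minimal two-cluster case", {
  pb_a <- matrix(rnorm(30), 1, 30, dimnames = list("only", paste0("g", 1:30)))
  pb_b <- pb_a + rnorm(30, sd = 0.1)
  rownames(pb_b) <- "match"
  res <- correspondence(pb_a, pb_b)
  expect_identical(nrow(res$pairing), 1L)
  expect_identical(res$pairing$cluster_b, "match")
  expect_identical(nrow(res$linkage$merge), 1L)
})

test_that("combined pseudobulk columns are z-scored and invariant to row order", {
  set.seed(45)
  pb_a <- matrix(rnorm(4 * 25), 4, 25,
                 dimnames = list(paste0("a", 1:4), paste0("g", 1:25)))
  pb_b <- matrix(rnorm(3 * 25), 3, 25,
                 dimnames = list(paste0("b", 1:3), paste0("g", 1:25)))
  res <- correspondence(pb_a, pb_b)
  expect_true(all(abs(colMeans(res$pseudobulk)) < 1e-9))
  expect_true(all(abs(apply(res$pseudobulk, 2, sd) - 1) < 1e-9))

  perm <- c(3, 1, 2, 4)
  res2 <- correspondence(pb_a[perm, ], pb_b)
  p1 <- res$pairing[order(res$pairing$cluster_a), ]
  p2 <- res2$pairing[order(res2$pairing$cluster_a), ]
  rownames(p1) <- rownames(p2) <- NULL
  expect_equal(p1, p2)

  pb_b0 <- pb_b; pb_b0[, 1] <- pb_a[1, 1]; pb_a0 <- pb_a
  pb_a0[, 1] <- pb_a[1, 1]  # constant column across both species
  expect_warning(correspondence(pb_a0, pb_b0), "zero-variance")
})

test_that("planted homology is recovered and fold change raises similarity", {
  skip_if_not_installed("mclust")
  pair_sim <- function(fold, seed) {
    cfg <- small_gen(seed = seed, marker_fold_change = fold,
                     doublet_rate = 0)
    sim <- generate_two_species(cfg)
    nms <- lapply(list(A = sim$species_a, B = sim$species_b), lognormalize)
    labs <- lapply(nms, function(nm) sim$truth$cell_labels[nm$cell_ids])
    mks <- list(A = all_markers(nms$A, labs$A),
                B = all_markers(nms$B, labs$B))
    omap <- sim$truth$ortholog_map
    sh <- shared_marker_set(mks$A, mks$B, omap, n = 50)
    genes_b <- omap$gene_b[match(sh$genes, omap$gene_a)]
    pb_a <- pseudobulk(nms$A, labs$A, sh$genes)
    pb_b <- pseudobulk(nms$B, labs$B, genes_b)
    colnames(pb_b) <- sh$genes
    correspondence(pb_a, pb_b)
  }
  res <- pair_sim(4, 46)
  shared <- c("SMC", "EC", "FB", "Mac", "T")
  got <- res$pairing
  expect_true(all(got$cluster_b[match(shared, got$cluster_a)] == shared))
  hom_sim <- got$similarity[match(shared, got$cluster_a)]
  uniq_sim <- got$similarity[got$cluster_a == "uniqA1"]
  expect_lt(uniq_sim, min(hom_sim))

  mean_hom <- function(fold, seeds) {
    mean(vapply(seeds, function(s) {
      p <- pair_sim(fold, s)$pairing
      mean(p$similarity[match(shared, p$cluster_a)])
    }, numeric(1)))
  }
  sims <- vapply(c(1.5, 2, 4), function(f) mean_hom(f, 47:49), numeric(1))
  expect_true(all(diff(sims) > 0))
})
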