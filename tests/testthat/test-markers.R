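test_that("wilcoxon matches closed cases: separated and identical groups", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_identical(w$U, 0)
  expect_equal(w$p, 0.1, tolerance = 1e-12)  # 2/20 arrangements as extreme

  x <- c(2, 5, 9, 1)
  w2 <- wilcoxon_rank_sum(x, x)
  expect_equal(w2$U, length(x)^2 / 2)
  expect_equal(w2$p, 1)
})

test_that("exact p equals brute-force enumeration on random small samples", {
  set.seed(10)
  for (i in 1:200) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    w <- wilcoxon_rank_sum(x, y, mode = "auto")
    expect_equal(w$p, enum_wilcox_p(x, y), tolerance = 1e-12)
  }
  # tied data under forced exact mode also matches enumeration
  for (i in 1:50) {
    x <- sample(0:2, 4, replace = TRUE); y <- sample(0:2, 4, replace = TRUE)
    w <- wilcoxon_rank_sum(x, y, mode = "exact")
    expect_equal(w$p, enum_wilcox_p(x, y), tolerance = 1e-12)
  }
})

test_that("wilcoxon is symmetric and U complements across group swap", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnbinom(8, mu = 2, size = 1); y <- rnbinom(10, mu = 2, size = 1)
    wxy <- wilcoxon_rank_sum(x, y); wyx <- wilcoxon_rank_sum(y, x)
    expect_equal(wxy$p, wyx$p, tolerance = 1e-12)
    expect_equal(wxy$U + wyx$U, length(x) * length(y))
  }
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("approximate p agrees with the exact tail for moderate samples", {
  set.seed(12)
  x <- rnorm(15); y <- rnorm(15) + 1
  pe <- wilcoxon_rank_sum(x, y, mode = "auto")$p   # 225 <= 400: exact
  pa <- wilcoxon_rank_sum(x, y, mode = "approx")$p
  expect_lt(abs(pe - pa), 0.01)
})

test_that("planted markers are detected with positive fold change and small q", {
  cfg <- generator_config(cells_per_type_per_condition =
                            c(control = 100, aneurysm = 100),
                          doublet_rate = 0, seed = 31)
  sim <- generate_two_species(cfg)
  nm <- lognormalize(sim$species_a)
  labels <- sim$truth$cell_labels[nm$cell_ids]
  mt <- cluster_markers(nm, labels, "SMC")
  planted <- intersect(sim$truth$planted_markers$SMC, nm$gene_ids)
  hits <- mt[mt$gene %in% planted, ]
  expect_identical(nrow(hits), length(planted))
  expect_true(all(hits$avg_log2FC > 0))
  expect_true(all(hits$p_adj_BH < 0.05))
  # planted markers lead the fold-change ranking
  expect_true(all(planted %in% top_n_markers(mt, length(planted))))
})

test_that("null genes are neither inflated nor ranked as markers", {
  # identically distributed gene in/out: small fold change, p rarely < .05
  set.seed(32)
  n_sig <- 0; n_rep <- 60
  for (i in 1:n_rep) {
    x <- log1p(rnbinom(60, mu = 1, size = 1))
    lab <- setNames(rep(c("a", "b"), each = 30), paste0("c", 1:60))
    nm <- norm_matrix(matrix(x, 1, dimnames = list("g1", names(lab))),
                      rep(1, 60), 1)
    nm$gene_ids <- "g1"
    mt <- cluster_markers(nm, lab, "a", only_pos = FALSE)
    expect_lt(abs(mt$avg_log2FC), 0.6)
    if (mt$p_value < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / n_rep, 0.1)
})

test_that("min_pct pre-filter removes scarcely detected genes", {
  m <- matrix(0, 2, 40)
  m[1, 1:20] <- 5          # well detected in cluster a (cells 1:20)
  m[2, 1] <- 5             # 5% of cluster a
  m[2, 21:40] <- 3
  cm <- count_matrix(Matrix::Matrix(m, sparse = TRUE), c("good", "rare"),
                     paste0("c", 1:40))
  nm <- lognormalize(cm)
  lab <- setNames(rep(c("a", "b"), each = 20), cm$cell_ids)
  mt <- cluster_markers(nm, lab, "a", min_pct = 0.1, only_pos = FALSE)
  expect_true("good" %in% mt$gene)
  expect_false("rare" %in% mt$gene)
})

test_that("top_n_markers truncates and breaks fold-change ties by gene id", {
  mt <- data.frame(cluster = "x", gene = c("B", "A", "C"),
                   U_statistic = 1, p_value = 0.01, p_adj_BH = 0.02,
                   avg_log2FC = c(2, 2, 1), pct_in = 1, pct_out = 0)
  mt <- mt[order(-mt$avg_log2FC, mt$gene), ]
  class(mt) <- c("MarkerTable", "data.frame")
  expect_identical(top_n_markers(mt, 5), c("A", "B", "C"))
  expect_identical(top_n_markers(mt, 2), c("A", "B"))
})

test_that("BH adjustment is monotone within a cluster", {
  sim <- generate_two_species(small_gen(seed = 33, doublet_rate = 0))
  nm <- lognormalize(sim$species_a)
  labels <- sim$truth$cell_labels[nm$cell_ids]
  mt <- cluster_markers(nm, labels, "EC", only_pos = FALSE)
  ord <- order(mt$p_value)
  expect_true(all(diff(mt$p_adj_BH[ord]) >= -1e-12))
  expect_true(all(mt$p_adj_BH >= mt$p_value - 1e-12))
})

test_that("all_markers equals per-cluster cluster_markers", {
  sim <- generate_two_species(small_gen(seed = 34, doublet_rate = 0))
  nm <- lognormalize(sim$species_a)
  labels <- sim$truth$cell_labels[nm$cell_ids]
  fast <- all_markers(nm, labels)
  for (cl in unique(labels)) {
    slow <- cluster_markers(nm, labels, cl)
    part <- fast[fast$cluster == cl, ]
    rownames(part) <- NULL
    expect_equal(part[, -1], slow[, -1], tolerance = 1e-10)
  }
})

test_that("dotplot statistics match a direct two-pass oracle", {
  cm <- random_cm(10, 30, mu = 1, seed = 35)
  nm <- lognormalize(cm)
  lab <- setNames(rep(c("a", "b", "c"), each = 10), cm$cell_ids)
  genes <- nm$gene_ids[1:5]
  st <- dotplot_stats(nm, lab, genes)
  dense <- as.matrix(nm$values)
  for (g in genes) {
    grand <- mean(dense[g, ])
    means <- vapply(c("a", "b", "c"),
                    function(cl) mean(dense[g, lab == cl]), numeric(1))
    for (cl in c("a", "b", "c")) {
      row <- st[st$gene == g & st$cluster == cl, ]
      expect_equal(row$fraction_above_mean,
                   mean(dense[g, lab == cl] > grand))
      expect_equal(row$mean_expression, unname(means[cl]))
      expect_equal(row$columnwise_z,
                   unname((means[cl] - mean(means)) / sd(means)))
    }
  }
})

test_that("dotplot degenerate cases: one cluster and an all-zero gene", {
  cm <- random_cm(4, 10, mu = 3, seed = 36)
  m <- as.matrix(cm$counts); m[1, ] <- 0
  cm <- count_matrix(Matrix::Matrix(m, sparse = TRUE), cm$gene_ids,
                     cm$cell_ids)
  nm <- lognormalize(cm)
  lab1 <- setNames(rep("only", 10), cm$cell_ids)
  st <- dotplot_stats(nm, lab1, cm$gene_ids)
  expect_true(all(st$columnwise_z == 0))
  expect_identical(st$fraction_above_mean[st$gene == cm$gene_ids[1]], 0)
  expect_error(dotplot_stats(nm, lab1, "nope"), "nope")
})
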