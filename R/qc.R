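#' Quality-control configuration
#'
#' Defaults follow the published filtering rules: genes detected in fewer
#' than 3 cells are removed; cells expressing fewer than 100 or more than
#' 4,000 genes, or with a mitochondrial count percentage above 5, are
#' removed (boundaries inclusive for retention). Mitochondrial genes are
#' recognized by symbol prefix.
#'
#' @param min_cells_per_gene genes must be detected (count > 0) in at least
#'   this many cells.
#' @param min_genes_per_cell,max_genes_per_cell closed retention interval
#'   for detected genes per cell.
#' @param max_mito_pct maximum mitochondrial count percentage retained.
#' @param mito_gene_prefixes prefixes identifying mitochondrial genes.
#' @param doublet_expected_rate fraction of cells flagged as doublets.
#' @param doublet_knn_k neighbors used by the doublet scorer.
#' @return A validated `QCConfig` list.
#' @export
qc_config <- function(min_cells_per_gene = 3L,
                      min_genes_per_cell = 100L,
                      max_genes_per_cell = 4000L,
                      max_mito_pct = 5.0,
                      mito_gene_prefixes = c("MT-", "mt-"),
                      doublet_expected_rate = 0.05,
                      doublet_knn_k = 20L) {
  cfg <- list(min_cells_per_gene = as.integer(min_cells_per_gene),
              min_genes_per_cell = as.integer(min_genes_per_cell),
              max_genes_per_cell = as.integer(max_genes_per_cell),
              max_mito_pct = max_mito_pct,
              mito_gene_prefixes = mito_gene_prefixes,
              doublet_expected_rate = doublet_expected_rate,
              doublet_knn_k = as.integer(doublet_knn_k))
  if (cfg$min_genes_per_cell < 0 ||
      cfg$min_genes_per_cell >= cfg$max_genes_per_cell)
    stop("invalid QCConfig: need 0 <= min_genes_per_cell < max_genes_per_cell")
  if (cfg$max_mito_pct < 0 || cfg$max_mito_pct > 100)
    stop("invalid QCConfig field 'max_mito_pct': must be in [0, 100]")
  if (cfg$doublet_expected_rate < 0 || cfg$doublet_expected_rate >= 1)
    stop("invalid QCConfig field 'doublet_expected_rate': must be in [0, 1)")
  structure(cfg, class = "QCConfig")
}

mito_genes <- function(gene_ids, prefixes = c("MT-", "mt-")) {
  hit <- rep(FALSE, length(gene_ids))
  for (p in prefixes) hit <- hit | startsWith(gene_ids, p)
  gene_ids[hit]
}

#' Per-cell QC metrics
#'
#' @param cm a `CountMatrix`.
#' @param cfg a `QCConfig` (used for the mitochondrial prefixes).
#' @return data.frame with `cell_id`, `n_genes` (detected genes),
#'   `n_counts`, `pct_mito`.
#' @export
qc_metrics <- function(cm, cfg = qc_config()) {
  n_genes <- Matrix::colSums(cm$counts > 0)
  n_counts <- Matrix::colSums(cm$counts)
  mt <- mito_genes(cm$gene_ids, cfg$mito_gene_prefixes)
  mito_counts <- if (length(mt))
    Matrix::colSums(cm$counts[cm$gene_ids %in% mt, , drop = FALSE]) else 0
  data.frame(cell_id = cm$cell_ids, n_genes = as.integer(n_genes),
             n_counts = as.numeric(n_counts),
             pct_mito = ifelse(n_counts > 0, 100 * mito_counts / n_counts, 0),
             stringsAsFactors = FALSE)
}

#' Remove genes detected in too few cells
#'
#' Retains exactly the genes with a non-zero count in at least
#' `cfg$min_cells_per_gene` cells; the cell set is unchanged and the input
#' is not modified.
#'
#' @param cm a `CountMatrix`.
#' @param cfg a `QCConfig`.
#' @return The filtered `CountMatrix`.
#' @export
filter_genes <- function(cm, cfg = qc_config()) {
  keep <- Matrix::rowSums(cm$counts > 0) >= cfg$min_cells_per_gene
  subset_counts(cm, genes = which(keep))
}

#' Remove low-quality cells
#'
#' Retains cells whose detected-gene count lies in the closed interval
#' `[min_genes_per_cell, max_genes_per_cell]` and whose mitochondrial
#' percentage is at most `max_mito_pct`. The gene set is unchanged.
#'
#' @param cm a `CountMatrix`.
#' @param cfg a `QCConfig`.
#' @return The filtered `CountMatrix`.
#' @export
filter_cells <- function(cm, cfg = qc_config()) {
  m <- qc_metrics(cm, cfg)
  keep <- m$n_genes >= cfg$min_genes_per_cell &
    m$n_genes <= cfg$max_genes_per_cell &
    m$pct_mito <= cfg$max_mito_pct
  subset_counts(cm, cells = which(keep))
}

#' Score and flag doublets with an artificial-doublet kNN scheme
#'
#' Simulates artificial doublets (25% of n, each the sum of the raw
#' counts of two random distinct cells, mirroring the generative process
#' of a real doublet), log-normalizes real and artificial cells together,
#' embeds them in PCA space, and scores every real cell by the fraction
#' of artificial cells among its k nearest neighbors. The top
#' `doublet_expected_rate` fraction of real cells by score (exactly
#' `round(rate * n)` cells; ties broken by cell order) is flagged.
#'
#' @param cm a `CountMatrix` (at least `2 * doublet_knn_k` cells).
#' @param cfg a `QCConfig`.
#' @param seed integer seed; identical seed gives identical scores.
#' @param n_pcs number of principal components for the embedding.
#' @param n_hvg number of variable genes used for the embedding.
#' @return data.frame with `cell_id`, `doublet_score` in [0, 1], and
#'   logical `doublet_flag`.
#' @export
detect_doublets <- function(cm, cfg = qc_config(), seed = 0L,
                            n_pcs = 10L, n_hvg = 1000L) {
  n <- length(cm$cell_ids)
  if (n < 2 * cfg$doublet_knn_k)
    stop("detect_doublets needs at least ", 2 * cfg$doublet_knn_k,
         " cells, got ", n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n_art <- max(1L, round(0.25 * n))
  p1 <- sample.int(n, n_art, replace = TRUE)
  p2 <- vapply(p1, function(i) sample(seq_len(n)[-i], 1), integer(1))
  art_counts <- cm$counts[, p1, drop = FALSE] + cm$counts[, p2, drop = FALSE]
  colnames(art_counts) <- paste0("artificial", seq_len(n_art))
  comb <- count_matrix(cbind(cm$counts, art_counts), cm$gene_ids,
                       c(cm$cell_ids, colnames(art_counts)))

  nm <- lognormalize(comb)
  hvg <- select_hvg(nm, n_hvg)
  sc <- scale_genes(nm, hvg)
  emb <- run_pca(sc, n_components = min(n_pcs, nrow(sc) - 1L, ncol(sc) - 1L),
                 seed = seed)
  coords <- emb$coords

  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  k <- cfg$doublet_knn_k
  is_art <- c(rep(FALSE, n), rep(TRUE, n_art))
  score <- vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    mean(is_art[nb])
  }, numeric(1))

  n_flag <- round(cfg$doublet_expected_rate * n)
  flag <- rep(FALSE, n)
  if (n_flag > 0) flag[order(-score)[seq_len(n_flag)]] <- TRUE
  data.frame(cell_id = cm$cell_ids, doublet_score = score,
             doublet_flag = flag, stringsAsFactors = FALSE)
}

#' Run the full QC stage: gene filter, cell filter, doublet filter
#'
#' Applies [filter_genes()], then [filter_cells()], then removes the cells
#' flagged by [detect_doublets()] (skipped with a warning when too few
#' cells remain for the scorer).
#'
#' @param cm a `CountMatrix`.
#' @param cfg a `QCConfig`.
#' @param seed seed for the doublet scorer.
#' @return list with `filtered` (`CountMatrix`) and `report` (per-cell QC
#'   data.frame for the input cells: metrics, doublet score and a `kept`
#'   flag).
#' @export
run_qc <- function(cm, cfg = qc_config(), seed = 0L) {
  report <- qc_metrics(cm, cfg)
  report$doublet_score <- NA_real_
  out <- filter_genes(cm, cfg)
  out <- filter_cells(out, cfg)
  kept <- cm$cell_ids %in% out$cell_ids
  if (length(out$cell_ids) >= 2 * cfg$doublet_knn_k &&
      cfg$doublet_expected_rate > 0) {
    dd <- detect_doublets(out, cfg, seed = seed)
    report$doublet_score[match(dd$cell_id, report$cell_id)] <- dd$doublet_score
    kept[cm$cell_ids %in% dd$cell_id[dd$doublet_flag]] <- FALSE
    out <- subset_counts(out, cells = which(!dd$doublet_flag))
  } else if (cfg$doublet_expected_rate > 0) {
    warning("too few cells for doublet detection; stage skipped")
  }
  report$kept <- kept
  list(filtered = out, report = report)
}
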