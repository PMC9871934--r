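#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Computes the Mann-Whitney U statistic using midranks for ties. In
#' `auto` mode the p-value is exact (from the null distribution of U) when
#' `n_x * n_y <= 400` and the data carry no ties, otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' `exact` forces the exact computation (falling back to full enumeration
#' of group assignments when ties are present; only feasible for small
#' samples); `approx` always uses the normal approximation.
#'
#' @param x,y non-empty numeric vectors.
#' @param mode one of `"auto"`, `"exact"`, `"approx"`.
#' @return list with `U` (statistic for `x`) and `p` (two-sided, in
#'   [0, 1]).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0)
    stop("wilcoxon_rank_sum: both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0

  use_exact <- switch(mode,
                      auto = !ties && nx * ny <= 400,
                      exact = TRUE,
                      approx = FALSE)
  if (use_exact) {
    if (!ties) {
      # symmetric null distribution of U: two-sided p doubles the smaller tail
      p <- 2 * stats::pwilcox(min(U, nx * ny - U), nx, ny)
    } else {
      p <- wilcox_enum_p(c(x, y), nx)
    }
  } else {
    mu <- nx * ny / 2
    N <- nx + ny
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p = min(max(p, 0), 1))
}

# exact two-sided p under ties by enumerating all C(N, nx) assignments
wilcox_enum_p <- function(pool, nx) {
  N <- length(pool)
  if (choose(N, nx) > 2e5)
    stop("exact mode with ties is only feasible for small samples")
  r <- rank(pool)
  mu <- nx * (N - nx) / 2
  combs <- utils::combn(N, nx)
  us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

#' One-vs-rest marker detection for a cluster
#'
#' Tests each gene's log-normalized expression in the cluster against all
#' other cells with the Wilcoxon rank-sum test (normal approximation).
#' Genes are pre-filtered to those detected in at least `min_pct` of the
#' cluster's cells. The average log2 fold change uses the convention
#' `log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`. P-values
#' are Benjamini-Hochberg adjusted across the genes tested within the
#' cluster. Rows are ordered by decreasing `avg_log2FC`, ties broken by
#' gene id.
#'
#' @param nm a `NormMatrix`.
#' @param labels named cluster labels (or `ClusterAssignment`).
#' @param cluster_id the cluster to test.
#' @param min_pct minimum detection fraction in the cluster (default 0.1).
#' @param only_pos keep only positive-fold-change genes (default TRUE).
#' @return A `MarkerTable` data.frame with columns `cluster`, `gene`,
#'   `U_statistic`, `p_value`, `p_adj_BH`, `avg_log2FC`, `pct_in`,
#'   `pct_out`.
#' @export
cluster_markers <- function(nm, labels, cluster_id, min_pct = 0.1,
                            only_pos = TRUE) {
  if (inherits(labels, "ClusterAssignment")) labels <- labels$labels
  labels <- labels[nm$cell_ids]
  in_cl <- which(labels == cluster_id)
  out_cl <- which(labels != cluster_id)
  if (length(in_cl) == 0) stop("cluster ", cluster_id, " is empty")
  if (length(out_cl) == 0) stop("complement of cluster ", cluster_id,
                                " is empty")
  x <- nm$values
  pct_in <- Matrix::rowSums(x[, in_cl, drop = FALSE] > 0) / length(in_cl)
  test_genes <- which(pct_in >= min_pct)
  if (length(test_genes) == 0)
    return(empty_marker_table())
  pct_out <- Matrix::rowSums(x[, out_cl, drop = FALSE] > 0) / length(out_cl)

  xi <- as.matrix(x[test_genes, in_cl, drop = FALSE])
  xo <- as.matrix(x[test_genes, out_cl, drop = FALSE])
  fc <- log2((rowMeans(expm1(xi)) + 1) / (rowMeans(expm1(xo)) + 1))

  stats_ <- t(vapply(seq_along(test_genes), function(i) {
    w <- wilcoxon_rank_sum(xi[i, ], xo[i, ], mode = "approx")
    c(w$U, w$p)
  }, numeric(2)))

  tab <- data.frame(cluster = cluster_id,
                    gene = nm$gene_ids[test_genes],
                    U_statistic = stats_[, 1],
                    p_value = stats_[, 2],
                    p_adj_BH = stats::p.adjust(stats_[, 2], method = "BH"),
                    avg_log2FC = fc,
                    pct_in = pct_in[test_genes],
                    pct_out = pct_out[test_genes],
                    stringsAsFactors = FALSE)
  if (only_pos) tab <- tab[tab$avg_log2FC > 0, , drop = FALSE]
  tab <- tab[order(-tab$avg_log2FC, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("MarkerTable", "data.frame")
  tab
}

empty_marker_table <- function() {
  tab <- data.frame(cluster = character(), gene = character(),
                    U_statistic = numeric(), p_value = numeric(),
                    p_adj_BH = numeric(), avg_log2FC = numeric(),
                    pct_in = numeric(), pct_out = numeric(),
                    stringsAsFactors = FALSE)
  class(tab) <- c("MarkerTable", "data.frame")
  tab
}

#' Markers for every cluster
#'
#' Equivalent to calling [cluster_markers()] for each cluster, but ranks
#' each gene once across all cells and reuses the rank sums for every
#' one-vs-rest comparison (normal approximation with tie and continuity
#' correction, as in [cluster_markers()]).
#'
#' @inheritParams cluster_markers
#' @return A `MarkerTable` data.frame concatenating the per-cluster
#'   results, in cluster order.
#' @export
all_markers <- function(nm, labels, min_pct = 0.1, only_pos = TRUE) {
  if (inherits(labels, "ClusterAssignment")) labels <- labels$labels
  labels <- labels[nm$cell_ids]
  cls <- sort(unique(labels))
  x <- as.matrix(nm$values)
  N <- ncol(x)
  ranks <- t(apply(x, 1, rank))
  tie_term <- apply(x, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  })
  expm1_means <- rowMeans(expm1(x))
  det <- x > 0

  out <- lapply(cls, function(cl) {
    in_cl <- which(labels == cl)
    out_cl <- which(labels != cl)
    if (length(out_cl) == 0) stop("complement of cluster ", cl, " is empty")
    nx <- length(in_cl); ny <- length(out_cl)
    pct_in <- rowMeans(det[, in_cl, drop = FALSE])
    keep <- which(pct_in >= min_pct)
    if (length(keep) == 0) return(empty_marker_table())
    pct_out <- rowMeans(det[keep, out_cl, drop = FALSE])
    mean_in <- rowMeans(expm1(x[keep, in_cl, drop = FALSE]))
    mean_out <- (expm1_means[keep] * N - mean_in * nx) / ny
    fc <- log2((mean_in + 1) / (mean_out + 1))

    U <- rowSums(ranks[keep, in_cl, drop = FALSE]) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term[keep] / (N * (N - 1)))
    z <- ifelse(sigma2 > 0,
                (U - mu - sign(U - mu) * 0.5) / sqrt(pmax(sigma2, 1e-300)), 0)
    p <- pmin(1, 2 * stats::pnorm(-abs(z)))
    tab <- data.frame(cluster = cl, gene = nm$gene_ids[keep],
                      U_statistic = U, p_value = p,
                      p_adj_BH = stats::p.adjust(p, method = "BH"),
                      avg_log2FC = fc, pct_in = pct_in[keep],
                      pct_out = pct_out, stringsAsFactors = FALSE)
    if (only_pos) tab <- tab[tab$avg_log2FC > 0, , drop = FALSE]
    tab[order(-tab$avg_log2FC, tab$gene), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("MarkerTable", "data.frame")
  out
}

#' Top-n genes of a marker table
#'
#' Returns the first `min(n, rows)` genes in the table's ordering
#' (decreasing average log2 fold change, ties by gene id). With a
#' multi-cluster table, pass `cluster_id` to restrict first.
#'
#' @param mt a `MarkerTable`.
#' @param n number of genes.
#' @param cluster_id optional cluster restriction.
#' @return Character vector of gene identifiers.
#' @export
top_n_markers <- function(mt, n, cluster_id = NULL) {
  stopifnot(n >= 1)
  if (!is.null(cluster_id)) mt <- mt[mt$cluster == cluster_id, , drop = FALSE]
  utils::head(mt$gene, n)
}

#' Dot-plot summary statistics
#'
#' For each (cluster, gene): the fraction of the cluster's cells whose
#' expression exceeds the gene's grand mean over all cells (circle size),
#' the cluster mean expression (color), and the column-wise z-score of
#' cluster means per gene.
#'
#' @param nm a `NormMatrix`.
#' @param labels named cluster labels (or `ClusterAssignment`).
#' @param genes genes to summarize.
#' @return data.frame with `cluster`, `gene`, `fraction_above_mean`,
#'   `mean_expression`, `columnwise_z`.
#' @export
dotplot_stats <- function(nm, labels, genes) {
  if (inherits(labels, "ClusterAssignment")) labels <- labels$labels
  miss <- setdiff(genes, nm$gene_ids)
  if (length(miss))
    stop("unknown gene(s): ", paste(utils::head(miss, 10), collapse = ", "))
  labels <- labels[nm$cell_ids]
  x <- as.matrix(nm$values[match(genes, nm$gene_ids), , drop = FALSE])
  grand <- rowMeans(x)
  cls <- sort(unique(labels))
  rows <- do.call(rbind, lapply(cls, function(cl) {
    xi <- x[, labels == cl, drop = FALSE]
    data.frame(cluster = cl, gene = genes,
               fraction_above_mean = rowMeans(xi > grand),
               mean_expression = rowMeans(xi),
               stringsAsFactors = FALSE)
  }))
  # z-score of cluster means within each gene ("column-wise" over clusters)
  rows$columnwise_z <- stats::ave(rows$mean_expression, rows$gene,
                                  FUN = function(v) {
                                    s <- stats::sd(v)
                                    if (is.na(s) || s == 0) rep(0, length(v))
                                    else (v - mean(v)) / s
                                  })
  rownames(rows) <- NULL
  rows
}
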