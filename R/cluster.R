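#' Build a shared-nearest-neighbor kNN graph in PC space
#'
#' For every cell the k nearest neighbors by Euclidean distance in the
#' embedding are found; the edge set is the union of the directed kNN
#' relations and each edge is weighted by the Jaccard overlap of the two
#' endpoints' neighbor sets (each set including the cell itself).
#' Deterministic (ties in distance broken by cell index).
#'
#' @param emb an `Embedding` from [run_pca()], or a cells x d matrix.
#' @param k number of neighbors (default 20; must be < number of cells).
#' @return An undirected weighted `igraph` graph with one vertex per cell.
#' @export
knn_graph <- function(emb, k = 20L) {
  coords <- if (inherits(emb, "Embedding")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                   n, ")")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nb <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))

  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  jac <- vapply(seq_len(nrow(edges)), function(e) {
    a <- c(edges[e, 1], nb[edges[e, 1], ])
    b <- c(edges[e, 2], nb[edges[e, 2], ])
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- jac
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- rownames(coords) %||% as.character(seq_len(n))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster a cell graph by modularity optimization
#'
#' Runs Leiden community detection (modularity objective) at the given
#' resolution, seeded for reproducibility. Cluster labels are 0-based and
#' relabeled in order of decreasing cluster size.
#'
#' @param graph weighted undirected `igraph` graph from [knn_graph()].
#' @param resolution resolution parameter (default 0.5).
#' @param seed integer seed.
#' @param n_iterations Leiden refinement iterations.
#' @return A `ClusterAssignment`: list with `labels` (named 0-based integer
#'   vector), `resolution`, `k_neighbors` (NA if unknown), `modularity`.
#' @export
cluster_graph <- function(graph, resolution = 0.5, seed = 0L,
                          n_iterations = 5L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution,
                               weights = igraph::E(graph)$weight,
                               n_iterations = n_iterations)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relab[as.character(memb)])
  names(labels) <- igraph::V(graph)$name
  mod <- igraph::modularity(graph, memb, weights = igraph::E(graph)$weight)
  structure(list(labels = labels, resolution = resolution,
                 k_neighbors = NA_integer_, modularity = mod),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment:", length(unique(x$labels)), "clusters over",
      length(x$labels), "cells (resolution", x$resolution,
      ", modularity", round(x$modularity, 3), ")\n")
  invisible(x)
}

#' 2-D t-SNE embedding for visualization
#'
#' Calls Rtsne on the PC coordinates with perplexity
#' `min(30, (n - 1) / 3)`, seeded. Visualization only: downstream
#' statistics never depend on these coordinates.
#'
#' @param emb an `Embedding` or cells x d matrix (at least 5 cells).
#' @param seed integer seed.
#' @param perplexity optional override.
#' @return cells x 2 matrix of coordinates.
#' @export
embed_tsne <- function(emb, seed = 0L, perplexity = NULL) {
  coords <- if (inherits(emb, "Embedding")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  if (n < 5) stop("embed_tsne needs at least 5 cells, got ", n)
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- Rtsne::Rtsne(coords, dims = 2, perplexity = perplexity,
                      pca = FALSE, check_duplicates = FALSE)$Y
  rownames(out) <- rownames(coords)
  colnames(out) <- c("tSNE1", "tSNE2")
  out
}

#' Cell-type composition per sample and per condition
#'
#' @param labels named vector of cluster ids or cell-type names (names are
#'   cell ids), or a `ClusterAssignment`.
#' @param cell_meta per-cell data.frame with `sample` and `condition`
#'   columns, rownames = cell ids.
#' @return A `CompositionTable`: list with `by_sample` and `by_condition`,
#'   each containing `fractions` (rows sum to 1) and the underlying
#'   integer `counts`.
#' @export
composition <- function(labels, cell_meta) {
  if (inherits(labels, "ClusterAssignment")) labels <- labels$labels
  cells <- names(labels)
  if (is.null(cells)) stop("labels must be named by cell id")
  meta <- cell_meta[cells, , drop = FALSE]
  bad <- cells[is.na(meta$sample) | is.na(meta$condition)]
  if (length(bad))
    stop("missing sample/condition metadata for cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  tab_of <- function(group) {
    counts <- table(group, labels)
    fr <- counts / rowSums(counts)
    list(counts = as.matrix(unclass(counts)),
         fractions = as.matrix(unclass(fr)))
  }
  structure(list(by_sample = tab_of(meta$sample),
                 by_condition = tab_of(meta$condition)),
            class = "CompositionTable")
}

#' Name clusters by their best-scoring marker gene set
#'
#' Each cluster is assigned the cell-type name whose marker set has the
#' highest mean module score over the cluster's cells, mirroring
#' annotation by acknowledged lineage markers.
#'
#' @param nm a `NormMatrix`.
#' @param labels named cluster labels.
#' @param marker_sets named list: cell-type name -> marker gene vector.
#' @return Named character vector: cluster id -> cell-type name.
#' @export
annotate_clusters <- function(nm, labels, marker_sets) {
  if (inherits(labels, "ClusterAssignment")) labels <- labels$labels
  score <- vapply(marker_sets, function(set) {
    present <- intersect(set, nm$gene_ids)
    if (!length(present)) return(rep(NA_real_, length(unique(labels))))
    s <- Matrix::colMeans(nm$values[match(present, nm$gene_ids), ,
                                    drop = FALSE])
    vapply(sort(unique(labels)), function(cl) mean(s[labels == cl]),
           numeric(1))
  }, numeric(length(unique(labels))))
  if (is.null(dim(score))) score <- matrix(score, nrow = 1)
  rownames(score) <- as.character(sort(unique(labels)))
  best <- colnames(score)[apply(score, 1, which.max)]
  stats::setNames(best, rownames(score))
}
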