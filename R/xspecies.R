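#' Load and resolve a one-to-one ortholog map
#'
#' Reads a two-column TSV (species-A gene, species-B gene; header
#' optional). Many-to-many entries are resolved by keeping only pairs
#' whose genes each occur exactly once in the raw map; pairs involving
#' genes absent from either supplied gene universe are dropped. Counts of
#' dropped pairs are reported via `message()`.
#'
#' @param path TSV path, or a data.frame with two columns.
#' @param genes_a,genes_b optional gene universes of the two datasets;
#'   pairs outside them are dropped.
#' @return An `OrthologMap`: data.frame with columns `gene_a`, `gene_b`,
#'   each identifier appearing at most once.
#' @export
load_orthologs <- function(path, genes_a = NULL, genes_b = NULL) {
  if (is.character(path)) {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
    if (ncol(raw) < 2)
      stop("ortholog map must have at least 2 columns, found ", ncol(raw))
    raw <- raw[, 1:2]
    # drop a header line if present (second row-style heuristics avoided:
    # a header is any first line repeated nowhere and matching no dataset)
    if (!is.null(genes_a) &&
        !(raw[1, 1] %in% genes_a) && nrow(raw) > 1 &&
        all(raw[-1, 1] %in% genes_a)) raw <- raw[-1, ]
  } else {
    raw <- as.data.frame(path)[, 1:2]
  }
  names(raw) <- c("gene_a", "gene_b")
  raw$gene_a <- as.character(raw$gene_a)
  raw$gene_b <- as.character(raw$gene_b)
  n_raw <- nrow(raw)

  multi <- raw$gene_a %in% raw$gene_a[duplicated(raw$gene_a)] |
    raw$gene_b %in% raw$gene_b[duplicated(raw$gene_b)]
  out <- raw[!multi, , drop = FALSE]
  n_multi <- sum(multi)

  n_absent <- 0L
  if (!is.null(genes_a)) {
    keep <- out$gene_a %in% genes_a
    n_absent <- n_absent + sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  if (!is.null(genes_b)) {
    keep <- out$gene_b %in% genes_b
    n_absent <- n_absent + sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  message("ortholog map: ", n_raw, " raw pairs; dropped ", n_multi,
          " many-to-many and ", n_absent, " absent-gene pairs; kept ",
          nrow(out))
  rownames(out) <- NULL
  class(out) <- c("OrthologMap", "data.frame")
  out
}

translate_b_to_a <- function(genes_b, omap) {
  idx <- match(genes_b, omap$gene_b)
  omap$gene_a[idx]
}

#' Cross-species shared marker set by top-n intersection
#'
#' For each cell type present in both marker tables (or each pair in
#' `type_pairing`), the top `n` genes per species are taken, species-B
#' genes are translated through the ortholog map, and the two lists are
#' intersected. The result is the union of the per-type intersections
#' (species-A identifiers), de-duplicated, ordered by first appearance by
#' type then gene.
#'
#' @param markers_a,markers_b `MarkerTable`s whose `cluster` column holds
#'   cell-type names.
#' @param omap an `OrthologMap`.
#' @param n top-gene count per type and species (default 50).
#' @param type_pairing optional data.frame (`type_a`, `type_b`) pairing
#'   differently named types; defaults to name identity.
#' @return list with `genes` (species-A ids) and `per_type` (named list of
#'   per-type intersections).
#' @export
shared_marker_set <- function(markers_a, markers_b, omap, n = 50L,
                              type_pairing = NULL) {
  if (is.null(type_pairing)) {
    shared <- intersect(unique(markers_a$cluster), unique(markers_b$cluster))
    if (length(shared) == 0)
      stop("no shared cell-type names between the marker tables; ",
           "supply type_pairing")
    type_pairing <- data.frame(type_a = shared, type_b = shared,
                               stringsAsFactors = FALSE)
  }
  per_type <- list()
  for (i in seq_len(nrow(type_pairing))) {
    ta <- type_pairing$type_a[i]; tb <- type_pairing$type_b[i]
    top_a <- top_n_markers(markers_a, n, cluster_id = ta)
    top_b <- top_n_markers(markers_b, n, cluster_id = tb)
    top_b_as_a <- stats::na.omit(translate_b_to_a(top_b, omap))
    per_type[[ta]] <- intersect(top_a, top_b_as_a)
  }
  genes <- unique(unlist(per_type, use.names = FALSE))
  list(genes = genes, per_type = per_type)
}

#' Pseudobulk profiles: mean expression per cluster
#'
#' @param nm a `NormMatrix`.
#' @param labels named cluster labels (or `ClusterAssignment`).
#' @param genes genes to include (must exist in `nm`).
#' @return clusters x genes matrix of mean log-normalized expression.
#' @export
pseudobulk <- function(nm, labels, genes) {
  if (inherits(labels, "ClusterAssignment")) labels <- labels$labels
  miss <- setdiff(genes, nm$gene_ids)
  if (length(miss))
    stop("unknown gene(s): ", paste(utils::head(miss, 10), collapse = ", "))
  labels <- labels[nm$cell_ids]
  cls <- sort(unique(labels))
  x <- nm$values[match(genes, nm$gene_ids), , drop = FALSE]
  out <- matrix(0, nrow = length(cls), ncol = length(genes))
  for (j in seq_along(cls)) {
    i <- which(labels == cls[j])
    if (length(i) == 0) stop("empty cluster: ", cls[j])
    out[j, ] <- Matrix::rowMeans(x[, i, drop = FALSE])
  }
  rownames(out) <- as.character(cls)
  colnames(out) <- genes
  out
}

#' Cross-species cluster correspondence by hierarchical clustering
#'
#' Stacks the two species' pseudobulk matrices (over the same ortholog
#' gene list, species-B columns already translated), z-scores every gene
#' column across the combined clusters, drops zero-variance columns with a
#' warning, then (i) hierarchically clusters all rows with distance
#' 1 - Pearson correlation and average linkage and (ii) pairs every
#' species-A cluster with its maximum-correlation species-B cluster.
#'
#' @param pb_a,pb_b clusters x genes pseudobulk matrices with identical
#'   column sets (species-A gene identifiers).
#' @param method linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return A `CorrespondenceResult`: list with `shared_genes`,
#'   `pseudobulk` (scaled stacked matrix; species-A rows prefixed `A:`,
#'   species-B rows `B:`), `linkage` (`hclust`), `pairing` (data.frame
#'   `cluster_a`, `cluster_b`, `similarity`), `similarity_matrix`
#'   (clusters_A x clusters_B Pearson correlations).
#' @export
correspondence <- function(pb_a, pb_b, method = "average") {
  genes <- colnames(pb_a)
  if (!identical(genes, colnames(pb_b)))
    stop("pseudobulk matrices must share an identical gene list")
  if (nrow(pb_a) + nrow(pb_b) < 2) stop("need at least 2 clusters in total")
  comb <- rbind(pb_a, pb_b)
  rownames(comb) <- c(paste0("A:", rownames(pb_a)),
                      paste0("B:", rownames(pb_b)))
  sds <- apply(comb, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene column(s) dropped")
    comb <- comb[, sds > 0, drop = FALSE]
  }
  scaled <- scale(comb)  # per-gene z-score across combined clusters
  attr(scaled, "scaled:center") <- NULL
  attr(scaled, "scaled:scale") <- NULL

  sim_all <- stats::cor(t(scaled))
  hc <- stats::hclust(stats::as.dist(1 - sim_all), method = method)

  na <- nrow(pb_a)
  sim <- sim_all[seq_len(na), na + seq_len(nrow(pb_b)), drop = FALSE]
  rownames(sim) <- rownames(pb_a)
  colnames(sim) <- rownames(pb_b)
  best <- apply(sim, 1, which.max)
  pairing <- data.frame(cluster_a = rownames(sim),
                        cluster_b = colnames(sim)[best],
                        similarity = sim[cbind(seq_len(na), best)],
                        stringsAsFactors = FALSE)
  structure(list(shared_genes = colnames(scaled), pseudobulk = scaled,
                 linkage = hc, pairing = pairing, similarity_matrix = sim),
            class = "CorrespondenceResult")
}

#' @export
print.CorrespondenceResult <- function(x, ...) {
  cat("CorrespondenceResult over", length(x$shared_genes), "ortholog genes\n")
  print(x$pairing)
  invisible(x)
}

#' Export a correspondence dendrogram as Newick
#'
#' @param res a `CorrespondenceResult`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_correspondence_tree <- function(res, path) {
  ape::write.tree(ape::as.phylo(res$linkage), file = path)
  invisible(path)
}
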