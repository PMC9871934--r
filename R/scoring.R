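#' Read a gene-set collection from a GMT file
#'
#' @param path GMT path (tab-separated: set name, description, genes...).
#' @return Named list of unique gene vectors (a `GeneSetCollection`).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets named list of gene vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, unique(sets[[nm]])), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Built-in T-cell state gene sets
#'
#' Convenience marker sets for calling T-cell immune states (naive,
#' resident, exhausted, cytotoxic, co-stimulatory), compiled from commonly
#' used human symbols. They are editable defaults for exploration, not an
#' authoritative signature collection; analyses of real data should supply
#' their own GMT.
#'
#' @return Named list of gene vectors.
#' @export
tcell_state_sets <- function() {
  list(
    naive = c("SELL", "CCR7", "LEF1", "TCF7"),
    resident = c("CD69", "RUNX3", "NR4A1"),
    exhausted = c("CTLA4", "TIGIT", "PDCD1", "LAG3", "HAVCR2", "TNFRSF9"),
    cytotoxic = c("NKG7", "GNLY", "GZMB", "GZMH", "GZMK", "IFNG"),
    costimulatory = c("ICOS", "CD28", "TNFRSF4", "TNFRSF18")
  )
}

#' Per-cell module score of a gene set
#'
#' `method = "mean"`: the per-cell arithmetic mean of the set's
#' log-normalized values (average expression of the gene set).
#' `method = "control_adjusted"`: the mean over the set minus the mean
#' over control genes; for every set gene, `n_ctrl` control genes are
#' drawn (seeded) from the same average-expression bin (`n_bins`
#' equal-frequency bins over all genes), so the expected score of a random
#' set on null data is 0.
#'
#' @param nm a `NormMatrix`.
#' @param set gene vector; genes absent from the matrix are dropped with a
#'   warning (at least one must remain).
#' @param method `"mean"` or `"control_adjusted"`.
#' @param n_bins expression bins for control matching (default 24).
#' @param n_ctrl control genes sampled per set gene (default 100).
#' @param seed seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(nm, set, method = c("mean", "control_adjusted"),
                         n_bins = 24L, n_ctrl = 100L, seed = 0L) {
  method <- match.arg(method)
  present <- intersect(set, nm$gene_ids)
  if (length(present) == 0)
    stop("none of the set's genes are present in the matrix")
  if (length(present) < length(set))
    warning(length(set) - length(present), " set gene(s) absent; dropped")
  x <- nm$values
  set_score <- Matrix::colMeans(x[match(present, nm$gene_ids), ,
                                  drop = FALSE])
  if (method == "mean") return(stats::setNames(set_score, nm$cell_ids))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  avg <- Matrix::rowMeans(x)
  bins <- as.integer(cut(rank(avg, ties.method = "first"),
                         breaks = min(n_bins, length(avg)),
                         labels = FALSE, include.lowest = TRUE))
  ctrl <- unlist(lapply(match(present, nm$gene_ids), function(gi) {
    pool <- which(bins == bins[gi])
    sample(pool, min(n_ctrl, length(pool)))
  }))
  ctrl_score <- Matrix::colMeans(x[unique(ctrl), , drop = FALSE])
  stats::setNames(set_score - ctrl_score, nm$cell_ids)
}

#' Compare module scores between two groups
#'
#' Wilcoxon rank-sum test of the scores of two groups, with group
#' medians.
#'
#' @param scores numeric vector of per-cell scores.
#' @param group_labels vector with exactly two distinct values, aligned
#'   with `scores`.
#' @param mode passed to [wilcoxon_rank_sum()].
#' @return list with `U`, `p`, `groups`, `medians`.
#' @export
compare_scores <- function(scores, group_labels, mode = "auto") {
  g <- unique(group_labels)
  if (length(g) != 2) stop("group_labels must define exactly two groups")
  x <- scores[group_labels == g[1]]
  y <- scores[group_labels == g[2]]
  w <- wilcoxon_rank_sum(x, y, mode = mode)
  list(U = w$U, p = w$p, groups = as.character(g),
       medians = c(stats::median(x), stats::median(y)))
}

#' Hypergeometric over-representation test of a query gene list
#'
#' For each set in the collection, the upper-tail hypergeometric
#' probability P(X >= overlap) of the observed overlap between query and
#' set, drawing `|query|` genes from a universe. Query genes outside the
#' universe are dropped with a warning; set genes outside the universe do
#' not count. P-values are Benjamini-Hochberg adjusted across the sets and
#' rows are sorted by p.
#'
#' @param query character vector of genes of interest.
#' @param collection named list of gene sets.
#' @param universe background gene vector.
#' @return data.frame with `set`, `set_size`, `overlap`, `p`, `p_adj_BH`.
#' @export
hypergeom_enrich <- function(query, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  out_of_univ <- setdiff(query, universe)
  if (length(out_of_univ)) {
    warning(length(out_of_univ), " query gene(s) outside universe; dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0) stop("empty query after universe restriction")
  N <- length(universe)
  n_draw <- length(query)
  rows <- lapply(names(collection), function(nm) {
    K <- length(intersect(collection[[nm]], universe))
    k <- length(intersect(collection[[nm]], query))
    p <- if (k == 0) 1.0
    else stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj_BH <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, tab$set), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
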