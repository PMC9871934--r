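#' Construct a NormMatrix
#'
#' @param values genes x cells matrix of log-normalized expression
#'   (`dgCMatrix` or dense).
#' @param library_sizes per-cell total counts before normalization.
#' @param scale_factor scale factor used.
#' @param cell_meta optional per-cell metadata data.frame.
#' @return A `NormMatrix` list with `values`, `gene_ids`, `cell_ids`,
#'   `library_sizes`, `scale_factor`, `cell_meta`.
#' @export
norm_matrix <- function(values, library_sizes, scale_factor,
                        cell_meta = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  structure(list(values = values, gene_ids = rownames(values),
                 cell_ids = colnames(values),
                 library_sizes = library_sizes,
                 scale_factor = scale_factor,
                 cell_meta = cell_meta),
            class = "NormMatrix")
}

#' @export
print.NormMatrix <- function(x, ...) {
  cat("NormMatrix:", length(x$gene_ids), "genes x", length(x$cell_ids),
      "cells (scale factor", x$scale_factor, ")\n")
  invisible(x)
}

#' Log-normalize counts
#'
#' Each entry becomes `ln(1 + count * scale_factor / library_size)` where
#' the library size is the cell's total count. Zeros stay zero and sparsity
#' is preserved. The transform is invariant to scaling a cell's counts by a
#' constant.
#'
#' @param cm a `CountMatrix`.
#' @param scale_factor scale factor (default 1e4).
#' @return A `NormMatrix`.
#' @export
lognormalize <- function(cm, scale_factor = 1e4) {
  lib <- Matrix::colSums(cm$counts)
  if (any(lib == 0))
    stop("zero library size for cell(s): ",
         paste(utils::head(cm$cell_ids[lib == 0], 5), collapse = ", "))
  v <- cm$counts
  # column-scale in place on the sparse slots
  v@x <- log1p(v@x * scale_factor /
                 rep.int(lib, diff(v@p)))
  norm_matrix(v, lib, scale_factor, cell_meta = cm$cell_meta)
}

#' Select highly variable genes by binned standardized dispersion
#'
#' Genes are ranked by the within-bin z-score of `log(variance / mean)` of
#' their log-normalized expression, with genes assigned to `n_bins`
#' equal-frequency bins of mean expression. Undetected or zero-variance
#' genes rank last. Ties are broken lexicographically by gene identifier,
#' making the selection deterministic.
#'
#' @param nm a `NormMatrix`.
#' @param n_hvg number of genes to return (default 2000); truncated to the
#'   number of genes available.
#' @param n_bins number of equal-frequency mean-expression bins.
#' @return Character vector of gene identifiers, ranked most variable
#'   first.
#' @export
select_hvg <- function(nm, n_hvg = 2000L, n_bins = 20L) {
  stopifnot(n_hvg >= 1)
  x <- nm$values
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  ex2 <- Matrix::rowMeans(x^2)
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  disp <- ifelse(mu > 0 & v > 0, log(v / mu), NA)

  bins <- if (length(unique(mu)) <= n_bins) as.integer(factor(mu))
  else as.integer(cut(rank(mu, ties.method = "first"),
                      breaks = n_bins, labels = FALSE, include.lowest = TRUE))
  z <- rep(NA_real_, length(mu))
  for (b in unique(bins)) {
    i <- which(bins == b & !is.na(disp))
    if (length(i) == 0) next
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z[is.na(z)] <- -Inf
  ord <- order(-z, nm$gene_ids)
  nm$gene_ids[ord][seq_len(min(n_hvg, length(mu)))]
}

#' Center and scale genes, with clipping
#'
#' Each selected gene row is centered to mean 0 and scaled to unit
#' variance (zero-variance genes become all-zero rows), then values are
#' clipped to `[-clip, clip]`.
#'
#' @param nm a `NormMatrix`.
#' @param genes gene identifiers to scale (must exist in `nm`).
#' @param clip clipping bound (default 10).
#' @return Dense genes x cells matrix of scaled values.
#' @export
scale_genes <- function(nm, genes, clip = 10) {
  miss <- setdiff(genes, nm$gene_ids)
  if (length(miss))
    stop("unknown gene(s): ", paste(utils::head(miss, 10), collapse = ", "))
  x <- as.matrix(nm$values[match(genes, nm$gene_ids), , drop = FALSE])
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  x <- (x - mu) / ifelse(sd > 0, sd, 1)
  x[sd == 0, ] <- 0
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  rownames(x) <- genes
  x
}

#' Principal component analysis of scaled expression
#'
#' Exact SVD of the cells x genes matrix (genes are assumed centered, as
#' produced by [scale_genes()]). Component signs are fixed so the loading
#' with the largest magnitude is positive, making the result deterministic.
#' If the matrix rank is below `n_components`, the remaining components are
#' zero-padded with a warning.
#'
#' @param scaled genes x cells matrix from [scale_genes()].
#' @param n_components number of components (default 30).
#' @param seed accepted for interface stability; the exact solver is
#'   deterministic.
#' @return An `Embedding`: list with `coords` (cells x d),
#'   `explained_variance` (length d, non-increasing), `d`, and `loadings`.
#' @export
run_pca <- function(scaled, n_components = 30L, seed = 0L) {
  x <- t(scaled)  # cells x genes
  n_components <- as.integer(n_components)
  if (n_components > min(dim(x)))
    stop("n_components (", n_components, ") exceeds min(dim) = ", min(dim(x)))
  s <- svd(x, nu = n_components, nv = n_components)
  dvals <- s$d[seq_len(n_components)]
  ev <- dvals^2 / max(1, nrow(x) - 1)
  rank_tol <- max(dim(x)) * max(s$d) * .Machine$double.eps
  low <- dvals < rank_tol
  if (any(low)) {
    warning("rank below n_components; ", sum(low),
            " components padded with zero variance")
    ev[low] <- 0
  }
  coords <- s$u %*% diag(dvals, n_components)
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(n_components)) {
    l <- s$v[, j]
    if (l[which.max(abs(l))] < 0) {
      s$v[, j] <- -l
      coords[, j] <- -coords[, j]
    }
  }
  coords[, low] <- 0
  rownames(coords) <- colnames(scaled)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  structure(list(coords = coords, explained_variance = ev,
                 d = n_components, loadings = s$v),
            class = "Embedding")
}

#' Merge per-sample normalized matrices on their common gene set
#'
#' Genes are intersected across samples, matrices concatenated
#' column-wise, and a `sample` covariate attached (existing metadata is
#' kept). Highly variable genes should then be re-selected on the merged
#' matrix.
#'
#' @param per_sample list of `NormMatrix` objects.
#' @param sample_names names for the samples (defaults to list names or
#'   `sample1`, `sample2`, ...).
#' @return A merged `NormMatrix` with a `sample` column in `cell_meta`.
#' @export
harmonize <- function(per_sample, sample_names = NULL) {
  stopifnot(length(per_sample) >= 1)
  if (length(per_sample) == 1) return(per_sample[[1]])
  if (is.null(sample_names))
    sample_names <- if (!is.null(names(per_sample))) names(per_sample)
  else paste0("sample", seq_along(per_sample))
  genes <- Reduce(intersect, lapply(per_sample, `[[`, "gene_ids"))
  if (length(genes) == 0) stop("empty gene intersection across samples")
  vals <- do.call(cbind, lapply(per_sample, function(nm)
    nm$values[match(genes, nm$gene_ids), , drop = FALSE]))
  rownames(vals) <- genes
  # cell ids may collide across samples; suffix repeats like the 10x reader
  colnames(vals) <- dedup_ids(unlist(lapply(per_sample, `[[`, "cell_ids"),
                                     use.names = FALSE))
  lib <- unlist(lapply(per_sample, `[[`, "library_sizes"), use.names = FALSE)
  meta <- do.call(rbind, lapply(seq_along(per_sample), function(i) {
    nm <- per_sample[[i]]
    m <- nm$cell_meta
    if (is.null(m)) m <- data.frame(row.names = nm$cell_ids)
    if (is.null(m$sample) || all(is.na(m$sample))) m$sample <- sample_names[i]
    m[, union("sample", names(m)), drop = FALSE]
  }))
  rownames(meta) <- colnames(vals)
  norm_matrix(vals, lib, per_sample[[1]]$scale_factor, cell_meta = meta)
}
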