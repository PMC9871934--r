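#' Construct a CountMatrix
#'
#' A `CountMatrix` bundles a sparse genes x cells matrix of non-negative
#' integer UMI counts with unique gene and cell identifiers and a per-cell
#' metadata table (sample, species, segment, condition).
#'
#' @param counts sparse (or dense) genes x cells matrix of non-negative
#'   integer counts. Coerced to `dgCMatrix`.
#' @param gene_ids character vector of gene identifiers, one per row.
#' @param cell_ids character vector of cell identifiers, one per column.
#' @param cell_meta data.frame with one row per cell. Missing columns among
#'   `sample`, `species`, `segment`, `condition` are filled with `NA`.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (`dgCMatrix`), `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts),
                         cell_meta = NULL) {
  counts <- methods::as(methods::as(as(counts, "CsparseMatrix"), "generalMatrix"),
                        "dMatrix")
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length (", length(gene_ids), ") != nrow(counts) (",
         nrow(counts), ")")
  if (length(cell_ids) != ncol(counts))
    stop("cell_ids length (", length(cell_ids), ") != ncol(counts) (",
         ncol(counts), ")")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  v <- counts@x
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = cell_ids)
  }
  if (nrow(cell_meta) != length(cell_ids))
    stop("cell_meta must have one row per cell")
  for (col in c("sample", "species", "segment", "condition")) {
    if (is.null(cell_meta[[col]])) cell_meta[[col]] <- NA_character_
  }
  rownames(cell_meta) <- cell_ids
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids,
                 cell_ids = cell_ids, cell_meta = cell_meta),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", length(x$gene_ids), "genes x", length(x$cell_ids),
      "cells;", length(x$counts@x), "non-zero entries\n")
  sp <- unique(stats::na.omit(x$cell_meta$species))
  if (length(sp)) cat("species:", paste(sp, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by genes and/or cells
#'
#' @param cm a `CountMatrix`.
#' @param genes gene identifiers or row indices to keep (default all).
#' @param cells cell identifiers or column indices to keep (default all).
#' @return The subsetted `CountMatrix`; the input is not modified.
#' @export
subset_counts <- function(cm, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_along(cm$gene_ids) else genes
  ci <- if (is.null(cells)) seq_along(cm$cell_ids) else cells
  if (is.character(gi)) gi <- match(gi, cm$gene_ids)
  if (is.character(ci)) ci <- match(ci, cm$cell_ids)
  if (anyNA(gi)) stop("unknown gene identifiers")
  if (anyNA(ci)) stop("unknown cell identifiers")
  count_matrix(cm$counts[gi, ci, drop = FALSE],
               gene_ids = cm$gene_ids[gi], cell_ids = cm$cell_ids[ci],
               cell_meta = cm$cell_meta[ci, , drop = FALSE])
}

dedup_ids <- function(ids) {
  # duplicate identifiers get ".1", ".2", ... suffixes, first kept verbatim
  make.unique(ids, sep = ".")
}

#' Read a count matrix from a 10x-style MTX triplet or a dense CSV
#'
#' Accepts either a directory (or `matrix.mtx` path) holding the triplet
#' `matrix.mtx[.gz]` + `features.tsv[.gz]`/`genes.tsv[.gz]` +
#' `barcodes.tsv[.gz]`, or a dense CSV with genes as rows (first column gene
#' identifiers, header row of cell identifiers). Orientation is normalized
#' to genes x cells and duplicate identifiers are suffixed `.1`, `.2`, ...
#'
#' @param path directory containing the MTX triplet, or a `.mtx`/`.csv` file.
#' @param cell_meta optional per-cell metadata data.frame (or path to a CSV
#'   with a `cell_id` column) to attach.
#' @return A `CountMatrix`.
#' @export
read_counts <- function(path, cell_meta = NULL) {
  if (dir.exists(path)) {
    mtx <- first_existing(path, c("matrix.mtx", "matrix.mtx.gz"))
    if (is.null(mtx)) stop("no matrix.mtx[.gz] found in ", path)
    cm <- read_counts_mtx(mtx)
  } else if (grepl("\\.mtx(\\.gz)?$", path)) {
    cm <- read_counts_mtx(path)
  } else if (grepl("\\.csv(\\.gz)?$", path)) {
    cm <- read_counts_csv(path)
  } else {
    stop("unrecognized input: ", path,
         " (expected a directory, .mtx or .csv)")
  }
  if (!is.null(cell_meta)) {
    if (is.character(cell_meta))
      cell_meta <- utils::read.csv(cell_meta, stringsAsFactors = FALSE)
    idx <- match(cm$cell_ids, cell_meta$cell_id)
    if (anyNA(idx)) stop("cell_meta is missing ", sum(is.na(idx)), " cells")
    meta <- cell_meta[idx, setdiff(names(cell_meta), "cell_id"), drop = FALSE]
    cm <- count_matrix(cm$counts, cm$gene_ids, cm$cell_ids, meta)
  }
  cm
}

first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  NULL
}

read_tsv_col <- function(path, col = 1L) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  if (ncol(x) >= 2 && col == 2L) x[[2]] else x[[1]]
}

read_counts_mtx <- function(mtx_path) {
  dir <- dirname(mtx_path)
  feat <- first_existing(dir, c("features.tsv", "features.tsv.gz",
                                "genes.tsv", "genes.tsv.gz"))
  bc <- first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(feat) || is.null(bc))
    stop("MTX triplet incomplete in ", dir,
         ": need features/genes.tsv and barcodes.tsv")
  m <- Matrix::readMM(mtx_path)
  feats <- utils::read.table(feat, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  # 10x features.tsv: id, symbol[, type]; prefer the symbol column
  genes <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  cells <- read_tsv_col(bc)
  if (nrow(m) == length(cells) && ncol(m) == length(genes) &&
      length(genes) != length(cells)) {
    m <- Matrix::t(m)  # cells x genes on disk; normalize to genes x cells
  }
  if (nrow(m) != length(genes))
    stop("MTX rows (", nrow(m), ") do not match features (",
         length(genes), ")")
  if (ncol(m) != length(cells))
    stop("MTX columns (", ncol(m), ") do not match barcodes (",
         length(cells), ")")
  v <- m@x
  if (any(v != round(v))) stop("non-integer entries in ", mtx_path)
  count_matrix(m, dedup_ids(genes), dedup_ids(cells))
}

read_counts_csv <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (any(m != round(m))) stop("non-integer entries in ", path)
  count_matrix(Matrix::Matrix(m, sparse = TRUE), dedup_ids(genes),
               dedup_ids(colnames(m)))
}

#' Write a CountMatrix as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and (if metadata is
#' present) `cell_meta.csv` into `dir`.
#'
#' @param cm a `CountMatrix`.
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(id = cm$gene_ids, name = cm$gene_ids),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  if (ncol(cm$cell_meta) > 0) {
    meta <- cbind(cell_id = cm$cell_ids, cm$cell_meta)
    utils::write.csv(meta, file.path(dir, "cell_meta.csv"), row.names = FALSE)
  }
  invisible(dir)
}
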