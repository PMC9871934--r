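#' Configuration for the two-species synthetic count generator
#'
#' The generator emulates the structure the comparative analysis assumes:
#' two species whose cell types share orthologous marker programs, plus a
#' species-specific type per species, condition-dependent composition
#' shifts (smooth-muscle depletion, immune expansion in aneurysm), a
#' mitochondrial gene block, and a fraction of doublet barcodes.
#'
#' Counts are negative binomial with variance \eqn{\mu + \mu^2/\phi}
#' (\code{nb_dispersion} = \eqn{\phi}); planted marker genes of a cell type
#' have mean \code{baseline_mean * marker_fold_change} in that type and
#' \code{baseline_mean} elsewhere. Ortholog identifiers follow the
#' human/mouse symbol convention: species A gene \code{GENEk} pairs with
#' species B \code{genek}.
#'
#' @param n_shared_types number of cell types shared (homologous) between
#'   the species.
#' @param n_specific_types number of species-specific cell types per
#'   species (no homolog in the other species).
#' @param cells_per_type_per_condition named integer vector, cells per type
#'   per condition per species before composition multipliers.
#' @param n_ortholog_genes number of 1:1 ortholog genes.
#' @param n_species_specific_genes extra private genes per species.
#' @param n_marker_genes_per_type planted ortholog marker genes per type.
#' @param marker_fold_change fold elevation of marker means in their type.
#' @param baseline_mean negative-binomial mean of non-marker genes.
#' @param nb_dispersion negative-binomial dispersion (size) parameter.
#' @param mito_gene_count number of mitochondrial genes (prefix
#'   \code{MT-} in species A, \code{mt-} in species B).
#' @param mito_mean_pct expected mitochondrial percentage of per-cell
#'   counts, in (0, 100).
#' @param doublet_rate fraction of barcodes that are doublets, in [0, 1).
#' @param condition_shift named list: cell type -> named numeric vector of
#'   per-condition abundance multipliers (> 0). Types not listed keep
#'   multiplier 1. Defaults deplete SMC and expand immune types in
#'   \code{"aneurysm"}.
#' @param type_names names of the shared cell types.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated `GeneratorConfig` list.
#' @export
generator_config <- function(n_shared_types = 5,
                             n_specific_types = 1,
                             cells_per_type_per_condition =
                               c(control = 100, aneurysm = 100),
                             n_ortholog_genes = 800,
                             n_species_specific_genes = 100,
                             n_marker_genes_per_type = 40,
                             marker_fold_change = 4,
                             baseline_mean = 0.5,
                             nb_dispersion = 1,
                             mito_gene_count = 10,
                             mito_mean_pct = 2.5,
                             doublet_rate = 0.05,
                             condition_shift = NULL,
                             type_names = NULL,
                             seed = 1L) {
  if (is.null(type_names))
    type_names <- c("SMC", "EC", "FB", "Mac", "T", "B", "NK")[
      seq_len(min(n_shared_types, 7))]
  if (length(type_names) < n_shared_types)
    type_names <- c(type_names,
                    paste0("type", seq_len(n_shared_types - length(type_names))))
  if (is.null(condition_shift)) {
    condition_shift <- list()
    if ("SMC" %in% type_names) condition_shift$SMC <- c(aneurysm = 0.4)
    for (t in intersect(c("Mac", "T"), type_names))
      condition_shift[[t]] <- c(aneurysm = 1.5)
  }
  # YAML configs arrive as nested lists; flatten to named numeric vectors
  cells_per_type_per_condition <- unlist(cells_per_type_per_condition)
  condition_shift <- lapply(condition_shift, unlist)
  cfg <- list(n_shared_types = as.integer(n_shared_types),
              n_specific_types = as.integer(n_specific_types),
              cells_per_type_per_condition = cells_per_type_per_condition,
              n_ortholog_genes = as.integer(n_ortholog_genes),
              n_species_specific_genes = as.integer(n_species_specific_genes),
              n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
              marker_fold_change = marker_fold_change,
              baseline_mean = baseline_mean,
              nb_dispersion = nb_dispersion,
              mito_gene_count = as.integer(mito_gene_count),
              mito_mean_pct = mito_mean_pct,
              doublet_rate = doublet_rate,
              condition_shift = condition_shift,
              type_names = type_names,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "GeneratorConfig")
}

validate_generator_config <- function(cfg) {
  need_pos <- c("n_shared_types", "n_ortholog_genes",
                "n_marker_genes_per_type", "marker_fold_change",
                "baseline_mean", "nb_dispersion")
  for (f in need_pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("invalid GeneratorConfig field '", f, "': must be a positive number")
  for (f in c("n_specific_types", "n_species_specific_genes",
              "mito_gene_count"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("invalid GeneratorConfig field '", f, "': must be >= 0")
  if (is.null(names(cfg$cells_per_type_per_condition)) ||
      any(cfg$cells_per_type_per_condition < 1))
    stop("invalid GeneratorConfig field 'cells_per_type_per_condition': ",
         "named vector of positive counts required")
  if (cfg$mito_gene_count > 0 &&
      (cfg$mito_mean_pct <= 0 || cfg$mito_mean_pct >= 100))
    stop("invalid GeneratorConfig field 'mito_mean_pct': must be in (0, 100)")
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1)
    stop("invalid GeneratorConfig field 'doublet_rate': must be in [0, 1)")
  for (t in names(cfg$condition_shift))
    if (any(cfg$condition_shift[[t]] <= 0))
      stop("invalid GeneratorConfig field 'condition_shift': ",
           "multipliers must be > 0 (type ", t, ")")
  if (cfg$n_marker_genes_per_type *
        (cfg$n_shared_types + 2 * cfg$n_specific_types) > cfg$n_ortholog_genes)
    stop("invalid GeneratorConfig field 'n_ortholog_genes': too few ",
         "ortholog genes to plant disjoint marker sets")
  invisible(cfg)
}

ortho_gene_ids <- function(n, species) {
  if (species == "A") paste0("GENE", seq_len(n)) else paste0("gene", seq_len(n))
}

#' Generate a two-species synthetic dataset with planted ground truth
#'
#' Draws negative-binomial counts for two species whose shared cell types
#' express the same ortholog marker programs, applies condition composition
#' multipliers, adds a mitochondrial block contributing
#' \code{mito_mean_pct} percent of counts in expectation, and converts
#' \code{round(doublet_rate * n)} barcodes per species into doublets by
#' adding the counts of a second random cell.
#'
#' @param config a `GeneratorConfig` from [generator_config()].
#' @return A list with `species_a`, `species_b` (both `CountMatrix`) and
#'   `truth` (`SyntheticTruth`: `cell_labels`, `homology`,
#'   `planted_markers`, `doublet_flags`, `ortholog_map`).
#' @export
generate_two_species <- function(config) {
  validate_generator_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  # disjoint ortholog marker blocks: one per shared type, then one per
  # A-specific type, then one per B-specific type (A/B unique programs
  # must not coincide)
  n_blocks <- config$n_shared_types + 2 * config$n_specific_types
  marker_idx <- split(seq_len(n_blocks * config$n_marker_genes_per_type),
                      rep(seq_len(n_blocks), each = config$n_marker_genes_per_type))
  shared_names <- config$type_names[seq_len(config$n_shared_types)]
  spec_a <- if (config$n_specific_types > 0)
    paste0("uniqA", seq_len(config$n_specific_types)) else character()
  spec_b <- if (config$n_specific_types > 0)
    paste0("uniqB", seq_len(config$n_specific_types)) else character()

  mk_species <- function(species) {
    types <- c(shared_names, if (species == "A") spec_a else spec_b)
    ortho <- ortho_gene_ids(config$n_ortholog_genes, species)
    priv <- if (config$n_species_specific_genes > 0)
      paste0(if (species == "A") "PRIV" else "priv",
             seq_len(config$n_species_specific_genes)) else character()
    mito <- if (config$mito_gene_count > 0)
      paste0(if (species == "A") "MT-G" else "mt-g",
             seq_len(config$mito_gene_count)) else character()
    genes <- c(ortho, priv, mito)
    n_nonmito <- length(ortho) + length(priv)

    # cells per type x condition after composition multipliers
    conds <- names(config$cells_per_type_per_condition)
    cell_type <- character(); cell_cond <- character()
    for (ty in types) for (cd in conds) {
      mult <- 1
      cs <- config$condition_shift[[ty]]
      if (!is.null(cs) && cd %in% names(cs)) mult <- cs[[cd]]
      k <- max(1L, as.integer(round(config$cells_per_type_per_condition[[cd]] * mult)))
      cell_type <- c(cell_type, rep(ty, k))
      cell_cond <- c(cell_cond, rep(cd, k))
    }
    n_cells <- length(cell_type)

    # per-type mean vectors over non-mito genes
    mu_base <- rep(config$baseline_mean, n_nonmito)
    mito_mu <- if (config$mito_gene_count > 0) {
      tot <- sum(mu_base)
      rep(tot * config$mito_mean_pct / (100 - config$mito_mean_pct) /
            config$mito_gene_count, config$mito_gene_count)
    } else numeric()
    block_of <- function(i) {
      if (i <= config$n_shared_types) i
      else i + if (species == "A") 0L else config$n_specific_types
    }
    type_mu <- lapply(seq_along(types), function(i) {
      mu <- mu_base
      mu[marker_idx[[block_of(i)]]] <-
        config$baseline_mean * config$marker_fold_change
      c(mu, mito_mu)
    })
    names(type_mu) <- types

    counts <- matrix(0L, nrow = length(genes), ncol = n_cells)
    for (ty in types) {
      idx <- which(cell_type == ty)
      mu <- type_mu[[ty]]
      counts[, idx] <- matrix(
        stats::rnbinom(length(genes) * length(idx),
                       mu = rep(mu, times = length(idx)),
                       size = config$nb_dispersion),
        nrow = length(genes))
    }

    n_doub <- round(config$doublet_rate * n_cells)
    doublet <- rep(FALSE, n_cells)
    if (n_doub > 0) {
      hosts <- sample.int(n_cells, n_doub)
      for (h in hosts) {
        partner <- sample(setdiff(seq_len(n_cells), h), 1)
        counts[, h] <- counts[, h] + counts[, partner]
      }
      doublet[hosts] <- TRUE
    }

    ids <- sprintf("%s_cell%04d", species, seq_len(n_cells))
    meta <- data.frame(sample = paste0(species, "_", cell_cond),
                       species = if (species == "A") "speciesA" else "speciesB",
                       segment = "thoracic", condition = cell_cond,
                       stringsAsFactors = FALSE)
    cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                       gene_ids = genes, cell_ids = ids, cell_meta = meta)
    list(cm = cm, labels = stats::setNames(cell_type, ids),
         doublet = stats::setNames(doublet, ids), types = types)
  }

  a <- mk_species("A")
  b <- mk_species("B")

  homology <- stats::setNames(shared_names, shared_names)
  ids_a <- ortho_gene_ids(config$n_ortholog_genes, "A")
  ids_b <- ortho_gene_ids(config$n_ortholog_genes, "B")
  planted <- lapply(seq_len(config$n_shared_types + config$n_specific_types),
                    function(i) ids_a[marker_idx[[i]]])
  names(planted) <- c(shared_names, spec_a)
  planted_b <- lapply(seq_len(config$n_specific_types), function(j)
    ids_b[marker_idx[[config$n_shared_types + config$n_specific_types + j]]])
  names(planted_b) <- spec_b
  omap <- data.frame(gene_a = ortho_gene_ids(config$n_ortholog_genes, "A"),
                     gene_b = ortho_gene_ids(config$n_ortholog_genes, "B"),
                     stringsAsFactors = FALSE)

  truth <- structure(list(
    cell_labels = c(a$labels, b$labels),
    homology = homology,
    planted_markers = c(planted, planted_b),
    doublet_flags = c(a$doublet, b$doublet),
    ortholog_map = omap), class = "SyntheticTruth")

  list(species_a = a$cm, species_b = b$cm, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a generated two-species dataset to disk
#'
#' Writes one 10x-style MTX triplet per species (plus `cell_meta.csv`), an
#' ortholog map TSV and a truth JSON under `dir`.
#'
#' @param sim result of [generate_two_species()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_two_species <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$species_a, file.path(dir, "speciesA"))
  write_counts(sim$species_b, file.path(dir, "speciesB"))
  utils::write.table(sim$truth$ortholog_map, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(cell_labels = as.list(truth$cell_labels),
         homology = as.list(truth$homology),
         planted_markers = truth$planted_markers,
         doublet_flags = as.list(truth$doublet_flags)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
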