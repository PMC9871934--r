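#' Pipeline configuration
#'
#' Single configuration object for the end-to-end two-species analysis.
#' Defaults follow the published settings: 2,000 highly variable genes,
#' 30 principal components, clustering resolution 0.5, k = 20 neighbors,
#' top 5 markers displayed, top 50 per type for the cross-species
#' intersection, scale factor 1e4. Unknown fields are rejected.
#'
#' @param qc a `QCConfig` (or list of [qc_config()] arguments).
#' @param n_hvg,n_pcs,resolution,knn_k,top_n_display,top_n_xspecies,scale_factor
#'   numeric pipeline settings (see defaults).
#' @param simulate `NULL`, or a `GeneratorConfig` (or list of
#'   [generator_config()] arguments) to run on synthetic data.
#' @param input_a,input_b paths to per-species count inputs (MTX directory
#'   or CSV); ignored when `simulate` is given.
#' @param orthologs path to the ortholog TSV; ignored when simulating.
#' @param out output directory.
#' @param marker_sets optional named list (or YAML path) of cell-type
#'   marker genes used to name clusters; when simulating, the generator's
#'   planted markers are used by default.
#' @param do_tsne compute the 2-D visualization embedding (default TRUE).
#' @param seed top-level integer seed; stage s uses `seed + s`.
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(qc = qc_config(), n_hvg = 2000L, n_pcs = 30L,
                            resolution = 0.5, knn_k = 20L,
                            top_n_display = 5L, top_n_xspecies = 50L,
                            scale_factor = 1e4, simulate = NULL,
                            input_a = NULL, input_b = NULL,
                            orthologs = NULL, out = tempfile("orthocell_"),
                            marker_sets = NULL, do_tsne = TRUE, seed = 0L) {
  if (is.list(qc) && !inherits(qc, "QCConfig")) qc <- do.call(qc_config, qc)
  if (is.list(simulate) && !inherits(simulate, "GeneratorConfig"))
    simulate <- do.call(generator_config, simulate)
  cfg <- list(qc = qc, n_hvg = as.integer(n_hvg), n_pcs = as.integer(n_pcs),
              resolution = resolution, knn_k = as.integer(knn_k),
              top_n_display = as.integer(top_n_display),
              top_n_xspecies = as.integer(top_n_xspecies),
              scale_factor = scale_factor, simulate = simulate,
              input_a = input_a, input_b = input_b, orthologs = orthologs,
              out = out, marker_sets = marker_sets, do_tsne = do_tsne,
              seed = as.integer(seed))
  for (f in c("n_hvg", "n_pcs", "knn_k", "top_n_display", "top_n_xspecies"))
    if (cfg[[f]] < 1) stop("invalid PipelineConfig field '", f, "'")
  if (cfg$resolution <= 0 || cfg$scale_factor <= 0)
    stop("invalid PipelineConfig: resolution and scale_factor must be > 0")
  if (is.null(cfg$simulate) && (is.null(cfg$input_a) || is.null(cfg$input_b)))
    stop("PipelineConfig needs either 'simulate' or both input paths")
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys raise an error; known keys are passed to
#' [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the two-species pipeline end to end
#'
#' Stages: simulate (or read) -> QC -> normalize/HVG/scale/PCA -> cluster
#' (+ optional t-SNE) -> per-cluster markers -> cross-species
#' correspondence. Artifacts (filtered matrices, QC reports, labels,
#' composition tables, marker tables, pairing, similarity matrix, Newick
#' dendrogram, manifest JSON) are written under `config$out`. All
#' randomness derives from `config$seed` (stage s uses `seed + s`).
#'
#' @param config a `PipelineConfig`.
#' @return Invisibly, a list with the in-memory results: `qc`, `norm`,
#'   `embeddings`, `clusters`, `annotations`, `markers`, `composition`,
#'   `correspondence`, `manifest` (plus `sim` when simulating).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("orthocell")),
                   seed = config$seed, stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message("[", name, "] ", paste(names(list(...)), unlist(list(...)),
                                   sep = "=", collapse = " "))
  }

  # stage 1: inputs
  sim <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed + 1L
    sim <- generate_two_species(sim_cfg)
    write_two_species(sim, file.path(out_dir, "sim"))
    raw <- list(A = sim$species_a, B = sim$species_b)
    omap_raw <- sim$truth$ortholog_map
  } else {
    raw <- list(A = read_counts(config$input_a),
                B = read_counts(config$input_b))
    omap_raw <- config$orthologs
  }
  log_stage("input", genes_a = nrow(raw$A$counts), cells_a = ncol(raw$A$counts),
            genes_b = nrow(raw$B$counts), cells_b = ncol(raw$B$counts))

  # stage 2: QC per species
  qcres <- lapply(names(raw), function(sp)
    run_qc(raw[[sp]], config$qc, seed = config$seed + 2L))
  names(qcres) <- names(raw)
  for (sp in names(qcres)) {
    utils::write.csv(qcres[[sp]]$report,
                     file.path(out_dir, paste0("qc_report_", sp, ".csv")),
                     row.names = FALSE)
    write_counts(qcres[[sp]]$filtered,
                 file.path(out_dir, paste0("filtered_", sp)))
  }
  log_stage("qc",
            cells_a = ncol(qcres$A$filtered$counts),
            genes_a = nrow(qcres$A$filtered$counts),
            cells_b = ncol(qcres$B$filtered$counts),
            genes_b = nrow(qcres$B$filtered$counts))

  # stage 3: normalize, HVG, scale, PCA
  norm <- list(); embeddings <- list()
  for (sp in names(qcres)) {
    nm <- lognormalize(qcres[[sp]]$filtered, config$scale_factor)
    hvg <- select_hvg(nm, config$n_hvg)
    sc <- scale_genes(nm, hvg)
    npc <- min(config$n_pcs, nrow(sc) - 1L, ncol(sc) - 1L)
    embeddings[[sp]] <- run_pca(sc, npc, seed = config$seed + 3L)
    norm[[sp]] <- nm
    writeLines(hvg, file.path(out_dir, paste0("hvg_", sp, ".txt")))
  }
  log_stage("preprocess", n_hvg = config$n_hvg,
            n_pcs = embeddings$A$d)

  # stage 4: cluster (+ t-SNE)
  clusters <- list(); tsne <- list()
  for (sp in names(norm)) {
    g <- knn_graph(embeddings[[sp]], k = min(config$knn_k,
                                             ncol(norm[[sp]]$values) - 1L))
    clusters[[sp]] <- cluster_graph(g, resolution = config$resolution,
                                    seed = config$seed + 4L)
    if (isTRUE(config$do_tsne))
      tsne[[sp]] <- embed_tsne(embeddings[[sp]], seed = config$seed + 4L)
  }
  log_stage("cluster",
            clusters_a = length(unique(clusters$A$labels)),
            clusters_b = length(unique(clusters$B$labels)))

  # stage 5: annotation + markers + composition
  msets <- config$marker_sets
  if (is.character(msets)) msets <- yaml::read_yaml(msets)
  annotations <- list(); markers <- list(); comp <- list()
  for (sp in names(norm)) {
    sets <- if (!is.null(msets)) msets
    else if (!is.null(sim)) {
      om <- sim$truth$ortholog_map
      tr <- lapply(sim$truth$planted_markers, function(gs) {
        # planted sets carry species-A ids for shared programs; translate
        # any id through the ortholog map into this species' universe
        mapped <- ifelse(gs %in% norm[[sp]]$gene_ids, gs,
                         ifelse(sp == "B", om$gene_b[match(gs, om$gene_a)],
                                om$gene_a[match(gs, om$gene_b)]))
        mapped[!is.na(mapped) & mapped %in% norm[[sp]]$gene_ids]
      })
      tr[vapply(tr, length, integer(1)) > 0]
    } else NULL
    mk <- all_markers(norm[[sp]], clusters[[sp]])
    if (!is.null(sets)) {
      ann <- annotate_clusters(norm[[sp]], clusters[[sp]], sets)
      annotations[[sp]] <- ann
      mk$cluster <- unname(ann[as.character(mk$cluster)])
    }
    markers[[sp]] <- mk
    utils::write.csv(mk, file.path(out_dir, paste0("markers_", sp, ".csv")),
                     row.names = FALSE)
    lab <- clusters[[sp]]$labels
    named <- if (!is.null(annotations[[sp]]))
      stats::setNames(unname(annotations[[sp]][as.character(lab)]),
                      names(lab)) else lab
    comp[[sp]] <- composition(named, norm[[sp]]$cell_meta)
    utils::write.csv(comp[[sp]]$by_condition$fractions,
                     file.path(out_dir, paste0("composition_", sp, ".csv")))
    lab_df <- data.frame(cell_id = names(lab), cluster = unname(lab),
                         cell_type = if (!is.null(annotations[[sp]]))
                           unname(annotations[[sp]][as.character(lab)])
                         else NA_character_)
    utils::write.csv(lab_df, file.path(out_dir, paste0("labels_", sp, ".csv")),
                     row.names = FALSE)
  }
  log_stage("markers", rows_a = nrow(markers$A), rows_b = nrow(markers$B))

  # stage 6: cross-species correspondence
  omap <- load_orthologs(omap_raw, genes_a = norm$A$gene_ids,
                         genes_b = norm$B$gene_ids)
  shared <- shared_marker_set(markers$A, markers$B, omap,
                              n = config$top_n_xspecies)
  xres <- NULL
  if (length(shared$genes) >= 2) {
    lab_a <- annotated_labels(clusters$A, annotations$A)
    lab_b <- annotated_labels(clusters$B, annotations$B)
    genes_b <- omap$gene_b[match(shared$genes, omap$gene_a)]
    pb_a <- pseudobulk(norm$A, lab_a, shared$genes)
    pb_b <- pseudobulk(norm$B, lab_b, genes_b)
    colnames(pb_b) <- shared$genes
    xres <- correspondence(pb_a, pb_b)
    utils::write.csv(xres$pairing, file.path(out_dir, "pairing.csv"),
                     row.names = FALSE)
    utils::write.csv(xres$similarity_matrix,
                     file.path(out_dir, "similarity.csv"))
    utils::write.csv(xres$pseudobulk,
                     file.path(out_dir, "pseudobulk_scaled.csv"))
    write_correspondence_tree(xres, file.path(out_dir, "dendrogram.nwk"))
    writeLines(shared$genes, file.path(out_dir, "shared_genes.txt"))
    log_stage("xspecies", shared_genes = length(shared$genes),
              pairs = nrow(xres$pairing))
  } else {
    log_stage("xspecies", shared_genes = length(shared$genes), pairs = 0)
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$file_md5 <- as.list(tools::md5sum(files))
  names(manifest$file_md5) <- substring(files, nchar(out_dir) + 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, qc = qcres, norm = norm,
                 embeddings = embeddings, clusters = clusters, tsne = tsne,
                 annotations = annotations, markers = markers,
                 composition = comp, correspondence = xres,
                 shared_markers = shared, ortholog_map = omap,
                 manifest = manifest))
}

annotated_labels <- function(cl, ann) {
  lab <- cl$labels
  if (is.null(ann)) return(lab)
  stats::setNames(unname(ann[as.character(lab)]), names(lab))
}
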