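# End-to-end orchestration over a fixture directory: expression -> coexpr ->
# regnet -> evodist -> spatial -> integrate, writing TSV outputs and a JSON
# report with a manifest, summary statistics, and the seed for provenance.

#' Run the full integrative analysis on a fixture directory
#'
#' Consumes the file set written by [write_fixture()] (or any directory in
#' the same dialect) and executes every stage: cell QC and clustering,
#' toxin-cell classification, pseudo-bulk/TMM/clr divergence against the
#' bulk library, co-expression modules on toxin cells, promoter extraction
#' and PWM scanning into candidate-TF barcodes, tree-ensemble importance
#' weights, promoter/peptide neighbor-joining patristic distances, spatial
#' correlation and anterior-posterior ANOVA, and all pairwise-matrix
#' correlations (Jaccard vs spatial / co-expression / genomic distance,
#' promoter vs peptide patristic). Outputs are written as TSVs plus
#' `report.json`.
#'
#' @param input_dir fixture directory.
#' @param output_dir directory for outputs (created if needed).
#' @param seed integer seed controlling clustering, the tree ensemble, and
#'   Mantel permutations.
#' @param marker_ids epithelial marker genes (default LAMA3, EPCAM).
#' @param qc_min_counts,qc_min_genes cell QC thresholds.
#' @param min_module_size,merge_dissimilarity module detection parameters.
#' @param score_fraction PWM scan threshold (fraction of max score).
#' @param n_trees trees per target for the importance network.
#' @param n_permutations Mantel permutations for matrix correlations
#'   (default 0: plain Pearson tests, as in the source analysis).
#' @param shuffle_barcodes negative control: randomly permute the computed
#'   barcodes across toxin genes before the integrative correlations.
#' @return the report list (also written as `report.json`).
#' @export
run_pipeline <- function(input_dir, output_dir, seed = 1,
                         marker_ids = c("LAMA3", "EPCAM"),
                         qc_min_counts = 1000, qc_min_genes = 100,
                         min_module_size = 30, merge_dissimilarity = 0.2,
                         score_fraction = 0.85, n_trees = 500,
                         n_permutations = 0, shuffle_barcodes = FALSE) {
  required <- c("annotation.tsv", "genome.fasta", "promoters.fasta",
                "peptides.fasta", "motifs.txt", "counts.mtx", "bulk.tsv")
  missing <- required[!file.exists(file.path(input_dir, required))]
  if (length(missing))
    stop("missing inputs: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  manifest <- character(0)
  emit <- function(name, writer) {
    path <- file.path(output_dir, name)
    writer(path)
    manifest <<- c(manifest, name)
  }

  ann <- read_annotation(file.path(input_dir, "annotation.tsv"))
  toxin_ids <- ann$gene_id[ann$class == "toxin"]
  counts <- read_counts_mtx(input_dir)
  bulk_df <- read.delim(file.path(input_dir, "bulk.tsv"))
  bulk <- stats::setNames(bulk_df$count, bulk_df$gene_id)[rownames(counts)]

  ## expression -------------------------------------------------------------
  kept <- filter_cells(counts, qc_min_counts, qc_min_genes)
  norm <- pseudobulk_and_normalize(kept, bulk)
  div <- clr_divergence(norm$cpm[, "pseudobulk"], norm$cpm[, 2],
                        toxin_ids = intersect(toxin_ids, rownames(counts)))
  clusters <- cluster_cells(kept, k_neighbors = min(20, ncol(kept) - 1),
                            seed = seed)
  annotation_cells <- classify_toxin_cells(kept, clusters, marker_ids,
                                           intersect(toxin_ids,
                                                     rownames(kept)))
  toxin_cells <- annotation_cells$cell_id[annotation_cells$is_toxin_cell]
  emit("cell_annotation.tsv", function(f)
    write.table(annotation_cells, f, sep = "\t", quote = FALSE,
                row.names = FALSE))
  emit("divergence.tsv", function(f)
    write.table(data.frame(gene_id = names(div$residuals),
                           residual = unname(div$residuals),
                           is_toxin = names(div$residuals) %in% toxin_ids,
                           flagged = names(div$residuals) %in%
                             names(div$flags)[div$flags]),
                f, sep = "\t", quote = FALSE, row.names = FALSE))

  toxin_counts <- kept[, intersect(toxin_cells, colnames(kept)),
                       drop = FALSE]
  coexpr_mat <- spearman_coexpression(toxin_counts, toxin_ids)
  emit("coexpression.tsv", function(f) write_matrix_tsv(coexpr_mat, f))

  ## coexpr: modules on toxin cells -----------------------------------------
  expr_tc <- log1p(cpm_simple(toxin_counts))
  expressed <- rowSums(toxin_counts) > 0
  expr_tc <- expr_tc[expressed, , drop = FALSE]
  modules <- NULL
  if (nrow(expr_tc) >= 30 && ncol(expr_tc) >= 10) {
    sft <- pick_soft_threshold(expr_tc, powers_tested = 1:12)
    adj <- adjacency_matrix(expr_tc, sft$power)
    tom <- tom_similarity(adj)
    part <- detect_modules(tom, min_module_size = min(min_module_size,
                                                      nrow(tom)))
    part <- merge_modules(expr_tc, part, merge_dissimilarity)
    modules <- part
    emit("modules.tsv", function(f)
      write.table(data.frame(gene_id = names(part$assignment),
                             module = unname(part$assignment)),
                  f, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("soft_threshold.tsv", function(f)
      write.table(sft$table, f, sep = "\t", quote = FALSE,
                  row.names = FALSE))
  }

  ## regnet -----------------------------------------------------------------
  promoters <- extract_promoters(file.path(input_dir, "genome.fasta"), ann)
  pfms <- read_pfms(file.path(input_dir, "motifs.txt"))
  hits <- pwm_scan(promoters, pfms, score_fraction = score_fraction)
  # module TF set: TFs expressed among toxin cells sharing a module with a
  # toxin gene; when no module structure is available, every scanned TF is
  # eligible
  module_tfs <- names(pfms)
  if (!is.null(modules)) {
    a <- modules$assignment
    toxin_modules <- unique(a[intersect(names(a), toxin_ids)])
    toxin_modules <- setdiff(toxin_modules, "unassigned")
    in_mod <- names(a)[a %in% toxin_modules]
    co <- intersect(names(pfms), in_mod)
    if (length(co)) module_tfs <- co
  }
  assignment <- call_candidate_tfs(module_tfs, hits, toxin_ids)
  tf_expr <- intersect(names(pfms), rownames(kept))
  weights <- NULL
  if (length(tf_expr) >= 2 && ncol(toxin_counts) >= 10) {
    expr_all <- log1p(cpm_simple(toxin_counts))
    weights <- importance_network(expr_all, tf_expr,
                                  intersect(toxin_ids, rownames(expr_all)),
                                  n_trees = n_trees, seed = seed)
    emit("weights.tsv", function(f) write_matrix_tsv(weights, f))
  }
  emit("hits.tsv", function(f)
    write.table(hits, f, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("barcode.tsv", function(f)
    write.table(assignment$hit_counts, f, sep = "\t", quote = FALSE,
                row.names = FALSE))

  if (shuffle_barcodes) {
    assignment$barcode <- with_stream(seed, "shuffle", {
      stats::setNames(sample(assignment$barcode), names(assignment$barcode))
    })
  }

  ## grn --------------------------------------------------------------------
  ppi_path <- file.path(input_dir, "ppi.tsv")
  grn <- build_grn(assignment,
                   ppi_edges = if (file.exists(ppi_path)) ppi_path,
                   weights = weights)
  cent <- centralities(grn)
  emit("centralities.tsv", function(f)
    write.table(cent, f, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("grn_edges.tsv", function(f)
    write.table(grn$edges, f, sep = "\t", quote = FALSE, row.names = FALSE))

  ## evodist ----------------------------------------------------------------
  prom_d <- pairwise_distance(file.path(input_dir, "promoters.fasta"))
  pep_d <- pairwise_distance(file.path(input_dir, "peptides.fasta"))
  prom_pat <- patristic(neighbor_joining(prom_d))
  pep_pat <- patristic(neighbor_joining(pep_d))
  emit("promoter_patristic.tsv", function(f) write_matrix_tsv(prom_pat, f))
  emit("peptide_patristic.tsv", function(f) write_matrix_tsv(pep_pat, f))

  ## spatial ----------------------------------------------------------------
  spatial <- NULL
  img_dir <- file.path(input_dir, "images")
  if (dir.exists(img_dir)) {
    axis_file <- file.path(img_dir, "axis.txt")
    axis_dim <- if (file.exists(axis_file)) readLines(axis_file)[1] else "col"
    stack <- read_ion_images(img_dir, axis_dim = axis_dim)
    sp_cor <- spatial_correlation(stack)
    centroids <- axis_localization(stack)
    groups <- stats::setNames(ann$group, ann$gene_id)
    loc <- group_location_test(centroids, groups)
    spatial <- list(correlation = sp_cor, centroids = centroids, test = loc)
    emit("spatial_correlation.tsv", function(f) write_matrix_tsv(sp_cor, f))
    emit("centroids.tsv", function(f)
      write.table(data.frame(gene_id = names(centroids),
                             centroid = unname(centroids),
                             group = unname(groups[names(centroids)])),
                  f, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("location_test.tsv", function(f)
      write.table(data.frame(f_statistic = loc$f, p_value = loc$p), f,
                  sep = "\t", quote = FALSE, row.names = FALSE))
  }

  ## integrate --------------------------------------------------------------
  jac <- jaccard_matrix(assignment)
  gdist <- genomic_distance(ann, toxin_ids)
  pairs <- list(
    promoter_vs_peptide_patristic = list(prom_pat, pep_pat),
    jaccard_vs_coexpression = list(jac, unclass(coexpr_mat)),
    jaccard_vs_genomic_distance = list(jac, unclass(gdist)))
  if (!is.null(spatial)) {
    pairs$jaccard_vs_spatial <- list(jac, unclass(spatial$correlation))
    pairs$genomic_distance_vs_spatial <-
      list(unclass(gdist), unclass(spatial$correlation))
    pairs$coexpression_vs_spatial <-
      list(unclass(coexpr_mat), unclass(spatial$correlation))
  }
  correlations <- do.call(rbind, lapply(names(pairs), function(nm) {
    res <- tryCatch(
      matrix_correlation(pairs[[nm]][[1]], pairs[[nm]][[2]],
                         n_permutations = n_permutations, seed = seed),
      error = function(e) list(r = NA_real_, p = NA_real_, n_pairs = 0L,
                               mantel_p = NA_real_, n_permutations = 0L))
    data.frame(comparison = nm, r = res$r, p = res$p, n_pairs = res$n_pairs,
               mantel_p = res$mantel_p)
  }))
  emit("correlations.tsv", function(f)
    write.table(correlations, f, sep = "\t", quote = FALSE,
                row.names = FALSE))
  emit("jaccard.tsv", function(f) write_matrix_tsv(jac, f))
  emit("genomic_distance.tsv", function(f) write_matrix_tsv(gdist, f))

  report <- list(
    seed = seed,
    n_cells_input = ncol(counts), n_cells_kept = ncol(kept),
    n_toxin_cells = length(toxin_cells),
    n_clusters = length(unique(clusters)),
    n_modules = if (!is.null(modules))
      length(setdiff(unique(modules$assignment), "unassigned")) else 0L,
    n_candidate_tfs = length(unique(unlist(assignment$barcode))),
    n_divergent_toxins = sum(div$flags),
    shuffled_barcodes = shuffle_barcodes,
    correlations = correlations,
    manifest = manifest)
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
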