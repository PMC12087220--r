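# Cell QC, pseudo-bulk + TMM normalization (edgeR), the clr /
# orthogonal-residual expression-divergence test, clustering, toxin-cell
# classification, and Spearman co-expression.

#' Filter cells by total counts and detected genes
#'
#' Retains cells with total counts >= `min_counts` AND number of distinct
#' expressed genes >= `min_genes` (both inclusive). The gene set is unchanged.
#'
#' @param counts genes x cells count matrix.
#' @param min_counts minimum total counts per cell (default 1000).
#' @param min_genes minimum number of detected genes per cell (default 100).
#' @return the filtered matrix; a message reports retained/removed cells.
#' @export
filter_cells <- function(counts, min_counts = 1000, min_genes = 100) {
  assert_count_matrix(counts)
  if (min_counts < 0 || min_genes < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  totals <- colSums(counts)
  ngene <- colSums(counts > 0)
  keep <- totals >= min_counts & ngene >= min_genes
  message(sprintf("filter_cells: retained %d of %d cells (removed %d)",
                  sum(keep), length(keep), sum(!keep)))
  if (!any(keep)) warning("all cells removed by QC filter", call. = FALSE)
  counts[, keep, drop = FALSE]
}

#' Pseudo-bulk construction and TMM normalization
#'
#' Sums cell counts per gene into one pseudo-bulk library, then computes
#' trimmed-mean-of-M-values scaling factors across the pseudo-bulk and all
#' bulk libraries (edgeR: 30% two-sided trim on M, 5% on A, weighted mean of
#' M, factors rescaled so their geometric mean is 1) and counts-per-million
#' CPM_g = count_g / (library size x factor) x 1e6.
#'
#' @param cell_counts genes x cells count matrix.
#' @param bulk_counts genes x libraries matrix (or named vector for a single
#'   bulk library) on the same gene index.
#' @return list with `cpm` (genes x libraries, pseudo-bulk first),
#'   `norm_factors`, `lib_sizes`, `pseudobulk` (raw summed counts).
#' @export
pseudobulk_and_normalize <- function(cell_counts, bulk_counts) {
  if (is.null(dim(bulk_counts)))
    bulk_counts <- matrix(bulk_counts, ncol = 1,
                          dimnames = list(names(bulk_counts), "bulk"))
  if (!identical(rownames(cell_counts), rownames(bulk_counts)))
    stop("cell and bulk matrices must share one gene index", call. = FALSE)
  pseudo <- rowSums(cell_counts)
  combined <- cbind(pseudobulk = pseudo, bulk_counts)
  zero <- colSums(combined) == 0
  if (any(zero))
    stop("library has zero total counts: ",
         paste(colnames(combined)[zero], collapse = ", "), call. = FALSE)
  d <- edgeR::DGEList(counts = combined)
  d <- edgeR::calcNormFactors(d, method = "TMM")
  cpm <- edgeR::cpm(d, normalized.lib.sizes = TRUE)
  list(cpm = cpm,
       norm_factors = stats::setNames(d$samples$norm.factors,
                                      colnames(combined)),
       lib_sizes = stats::setNames(d$samples$lib.size, colnames(combined)),
       pseudobulk = pseudo)
}

#' Centered log-ratio transform
#'
#' `clr(x)_g = ln(x_g) - mean_g(ln(x))`; requires strictly positive input.
#'
#' @param x positive numeric vector.
#' @return a vector summing to zero.
#' @export
clr <- function(x) {
  if (any(x <= 0)) stop("clr requires strictly positive values", call. = FALSE)
  lx <- log(x)
  lx - mean(lx)
}

#' Expression divergence of toxins between pseudo-bulk and bulk
#'
#' Both CPM profiles are clr-transformed (zeros replaced by adding a
#' pseudo-value, default half the smallest nonzero CPM). A total-least-squares
#' line (orthogonal residuals) is fitted through the non-toxin
#' (clr bulk, clr pseudo-bulk) points; each gene's divergence is its signed
#' orthogonal distance from that line. The null interval is the central
#' `percentile`% band of non-toxin residuals (for 99: the 0.5th-99.5th
#' percentiles); a toxin is flagged as divergent iff its residual falls
#' outside the band.
#'
#' @param pseudo,bulk named CPM vectors on one gene index.
#' @param toxin_ids toxin gene identifiers.
#' @param percentile central band width (default 99).
#' @param pseudo_value value added to zeros before clr; `NULL` = half the
#'   smallest nonzero CPM across both profiles.
#' @return a `divergence_report` list: `clr_pseudobulk`, `clr_bulk`,
#'   `fit_slope`, `fit_intercept`, `residuals`, `interval`, `flags`.
#' @export
clr_divergence <- function(pseudo, bulk, toxin_ids, percentile = 99,
                           pseudo_value = NULL) {
  if (!identical(names(pseudo), names(bulk)))
    stop("pseudo and bulk vectors must share one gene index", call. = FALSE)
  genes <- names(pseudo)
  if (!all(toxin_ids %in% genes))
    stop("unknown toxin ids: ",
         paste(setdiff(toxin_ids, genes), collapse = ", "), call. = FALSE)
  non_toxin <- setdiff(genes, toxin_ids)
  if (length(non_toxin) < 10)
    stop("need at least 10 non-toxin genes to form the null", call. = FALSE)
  if (is.null(pseudo_value)) {
    nz <- c(pseudo[pseudo > 0], bulk[bulk > 0])
    pseudo_value <- min(nz) / 2
  }
  cp <- clr(pseudo + ifelse(pseudo == 0, pseudo_value, 0))
  cb <- clr(bulk + ifelse(bulk == 0, pseudo_value, 0))

  # total least squares through non-toxin points: first principal axis
  x <- cb[non_toxin]; y <- cp[non_toxin]
  mx <- mean(x); my <- mean(y)
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE)
  dirv <- ev$vectors[, 1]
  if (abs(dirv[1]) < 1e-12)
    stop("degenerate fit: vertical principal axis", call. = FALSE)
  slope <- dirv[2] / dirv[1]
  intercept <- my - slope * mx
  # signed orthogonal distance (positive above the line)
  resid_all <- (cp - (intercept + slope * cb)) / sqrt(1 + slope^2)
  null_res <- resid_all[non_toxin]
  alpha <- (100 - percentile) / 2
  interval <- quantile(null_res, c(alpha, 100 - alpha) / 100, names = FALSE)
  flags <- resid_all[toxin_ids] < interval[1] | resid_all[toxin_ids] > interval[2]
  structure(list(clr_pseudobulk = cp, clr_bulk = cb,
                 fit_slope = slope, fit_intercept = intercept,
                 residuals = resid_all,
                 interval = stats::setNames(interval, c("lower", "upper")),
                 flags = stats::setNames(flags, toxin_ids)),
            class = "divergence_report")
}

cpm_simple <- function(counts) {
  sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
}

#' Cluster cells by PCA, kNN graph, and Louvain community detection
#'
#' log1p-CPM -> top principal components -> k-nearest-neighbour graph
#' (union of directed kNN relations) -> modularity-based Louvain communities.
#' Labels are `0..K-1` ordered by decreasing community size, deterministic
#' given the seed.
#'
#' @param counts genes x cells count matrix.
#' @param n_pcs number of principal components (default 30).
#' @param k_neighbors neighbours per cell (default 20; must be < #cells).
#' @param resolution Louvain resolution (default 1).
#' @param seed integer seed.
#' @return integer cluster labels named by cell.
#' @export
cluster_cells <- function(counts, n_pcs = 30, k_neighbors = 20,
                          resolution = 1, seed = 1) {
  assert_count_matrix(counts)
  nc <- ncol(counts)
  if (nc < 2) stop("need at least 2 cells to cluster", call. = FALSE)
  if (k_neighbors >= nc)
    stop("k_neighbors must be smaller than the number of cells",
         call. = FALSE)
  x <- t(log1p(cpm_simple(counts)))
  keep <- apply(x, 2, sd) > 0
  if (!any(keep)) {
    # all cells identical: one community
    return(stats::setNames(rep(0L, nc), colnames(counts)))
  }
  x <- x[, keep, drop = FALSE]
  npc <- min(n_pcs, ncol(x), nc - 1)
  pcs <- prcomp(x, center = TRUE, scale. = TRUE, rank. = npc)$x
  dmat <- as.matrix(dist(pcs))
  edges <- do.call(rbind, lapply(seq_len(nc), function(i) {
    nn <- order(dmat[i, ])[2:(k_neighbors + 1)]
    cbind(i, nn)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- with_stream(seed, "louvain",
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  stats::setNames(unname(relabel[as.character(memb)]), colnames(counts))
}

#' Classify toxin-producing cells by cluster
#'
#' A cluster is called toxin-producing iff its mean per-cell toxin count
#' fraction is >= `min_cluster_toxin_fraction` AND the fraction of its cells
#' detecting at least one epithelial marker is >= `min_marker_detect_fraction`
#' (the markers stand in for LAMA3/EPCAM-style secretory epithelium markers).
#' Cells inherit their cluster's call.
#'
#' @param counts genes x cells count matrix.
#' @param clusters labels from [cluster_cells()].
#' @param marker_ids epithelial marker gene ids.
#' @param toxin_ids toxin gene ids.
#' @param min_cluster_toxin_fraction cluster-mean toxin fraction threshold.
#' @param min_marker_detect_fraction marker-positive cell fraction threshold.
#' @return data.frame (cell_id, cluster, toxin_fraction, marker_score,
#'   is_toxin_cell).
#' @export
classify_toxin_cells <- function(counts, clusters, marker_ids, toxin_ids,
                                 min_cluster_toxin_fraction = 0.2,
                                 min_marker_detect_fraction = 0.5) {
  missing <- setdiff(c(marker_ids, toxin_ids), rownames(counts))
  if (length(missing))
    stop("ids absent from gene index: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stopifnot(identical(names(clusters), colnames(counts)))
  totals <- pmax(colSums(counts), 1)
  toxin_fraction <- colSums(counts[toxin_ids, , drop = FALSE]) / totals
  marker_pos <- colSums(counts[marker_ids, , drop = FALSE] > 0) >= 1
  marker_score <- colMeans(log1p(cpm_simple(counts))[marker_ids, ,
                                                     drop = FALSE])
  cl <- as.character(clusters)
  cluster_call <- vapply(unique(cl), function(k) {
    in_k <- cl == k
    mean(toxin_fraction[in_k]) >= min_cluster_toxin_fraction &&
      mean(marker_pos[in_k]) >= min_marker_detect_fraction
  }, logical(1))
  data.frame(cell_id = colnames(counts), cluster = unname(clusters),
             toxin_fraction = unname(toxin_fraction),
             marker_score = unname(marker_score),
             is_toxin_cell = unname(cluster_call[cl]))
}

#' Pairwise Spearman co-expression across cells
#'
#' Spearman rank correlation (average ranks for ties) between genes over
#' cells, computed on log1p-CPM.
#'
#' @param counts genes x cells count matrix.
#' @param gene_ids genes to correlate (default all).
#' @return a symmetric `pair_matrix` with unit diagonal; genes constant
#'   across cells yield missing values with a warning.
#' @export
spearman_coexpression <- function(counts, gene_ids = rownames(counts)) {
  if (ncol(counts) < 3)
    stop("need at least 3 cells for rank correlation", call. = FALSE)
  missing <- setdiff(gene_ids, rownames(counts))
  if (length(missing))
    stop("unknown gene ids: ", paste(missing, collapse = ", "), call. = FALSE)
  x <- t(log1p(cpm_simple(counts))[gene_ids, , drop = FALSE])
  const <- apply(x, 2, function(v) sd(v) == 0)
  rho <- suppressWarnings(cor(x, method = "spearman"))
  if (any(const)) {
    warning("constant genes yield undefined correlations: ",
            paste(gene_ids[const], collapse = ", "), call. = FALSE)
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  diag(rho) <- ifelse(const, NA_real_, 1)
  new_pair_matrix(rho, "spearman_coexpression", "similarity")
}
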