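# Weighted co-expression module detection: soft-threshold selection for
# scale-free topology, adjacency, topological overlap (TOM), fixed-height
# tree-cut module detection with a minimum size, eigengenes / module
# membership (kME), eigengene-based merging, and module-trait correlation.
# Formulas follow the standard weighted co-expression construction.

#' Co-expression adjacency matrix
#'
#' Unsigned: `a_ij = |cor(x_i, x_j)|^beta`; signed:
#' `a_ij = ((1 + cor) / 2)^beta`. The diagonal is set to 0 so that
#' connectivity `k_i = sum_j a_ij` excludes self-adjacency.
#'
#' @param expr genes x samples expression matrix (e.g. log1p-CPM).
#' @param beta soft-threshold power (>= 1).
#' @param signed use the signed transform (default FALSE).
#' @return symmetric genes x genes adjacency with zero diagonal; constant
#'   genes get zero adjacency with a warning.
#' @export
adjacency_matrix <- function(expr, beta, signed = FALSE) {
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  const <- apply(expr, 1, function(v) sd(v) == 0)
  if (all(const)) stop("expression matrix is constant", call. = FALSE)
  cc <- suppressWarnings(cor(t(expr)))
  if (any(const)) {
    warning("constant genes treated as uncorrelated: ",
            paste(rownames(expr)[const], collapse = ", "), call. = FALSE)
    cc[const, ] <- 0
    cc[, const] <- 0
  }
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 0
  a
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) n_bins <- max(2L, length(k) %/% 2L)
  breaks <- unique(quantile(k, seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(k, breaks, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0
  lx <- log10(km[ok]); ly <- log10(pk[ok])
  if (length(lx) < 3 || sd(lx) == 0 || sd(ly) == 0)
    return(list(r2 = 0, slope = 0))
  fit <- lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  r2 <- cor(lx, ly)^2
  list(r2 = if (slope > 0) 0 else r2, slope = slope)
}

#' Pick a soft-threshold power for scale-free topology
#'
#' For each candidate power: build the adjacency, compute connectivities,
#' bin log10(k) into 10 equal-occupancy bins and regress log10 p(k) on
#' log10 k. The fit index is the squared Pearson correlation, set to 0 when
#' the slope is positive. The chosen power is the smallest one reaching
#' `target_r2`; if none does, the power with maximal fit is returned with a
#' warning.
#'
#' @inheritParams adjacency_matrix
#' @param powers_tested candidate powers (default 1:20).
#' @param target_r2 scale-free fit target (default 0.8).
#' @return list with `table` (power, r2, slope, mean_k) and `power` (chosen).
#' @export
pick_soft_threshold <- function(expr, powers_tested = 1:20, target_r2 = 0.8,
                                signed = FALSE) {
  if (nrow(expr) < 30 || ncol(expr) < 10)
    stop("need >= 30 genes and >= 10 samples", call. = FALSE)
  if (any(powers_tested < 1)) stop("powers must be >= 1", call. = FALSE)
  rows <- lapply(powers_tested, function(b) {
    a <- adjacency_matrix(expr, b, signed = signed)
    k <- rowSums(a)
    f <- scale_free_fit(k)
    data.frame(power = b, r2 = f$r2, slope = f$slope, mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(tab$r2 >= target_r2)
  if (length(hit)) {
    power <- tab$power[hit[1]]
  } else {
    power <- tab$power[which.max(tab$r2)]
    warning(sprintf(
      "no power reached scale-free R^2 >= %.2f; using power %d (R^2 = %.2f)",
      target_r2, power, max(tab$r2)), call. = FALSE)
  }
  list(table = tab, power = power)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`.
#'
#' @param a symmetric adjacency in [0, 1] with zero diagonal.
#' @return symmetric TOM in [0, 1] with unit diagonal.
#' @export
tom_similarity <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  if (min(a) < 0 || max(a) > 1 || any(diag(a) != 0))
    stop("adjacency must lie in [0, 1] with a zero diagonal", call. = FALSE)
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by average-linkage clustering of TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a fixed
#' height; clusters smaller than `min_module_size` become "unassigned".
#' Modules are labelled `M1, M2, ...` by decreasing size.
#'
#' @param tom TOM from [tom_similarity()].
#' @param min_module_size smallest retained module (default 30).
#' @param cut_height tree-cut height on 1 - TOM (default 0.99).
#' @return a `module_partition` list with `assignment` (named gene -> label).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  genes <- rownames(tom)
  if (nrow(tom) < min_module_size) {
    warning("fewer genes than min_module_size; all unassigned", call. = FALSE)
    return(structure(list(assignment = stats::setNames(
      rep("unassigned", nrow(tom)), genes)), class = "module_partition"))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  assignment <- rep("unassigned", length(raw))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep])]
    for (i in seq_along(keep))
      assignment[raw == as.integer(keep[i])] <- paste0("M", i)
  }
  structure(list(assignment = stats::setNames(assignment, genes)),
            class = "module_partition")
}

module_eigengene <- function(expr_mod) {
  z <- t(scale(t(expr_mod)))
  z[is.na(z)] <- 0
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE, rank. = 1)
  e <- pc$x[, 1]
  # orient to correlate positively with the module's mean profile
  avg <- colMeans(z)
  if (sd(avg) > 0 && sd(e) > 0 && cor(e, avg) < 0) e <- -e
  if (sd(e) > 0) e <- e / sd(e)
  e
}

#' Eigengenes and module membership (kME)
#'
#' The eigengene is the first principal component of the module's
#' standardized expression, sign-oriented to correlate positively with the
#' module's mean profile and scaled to unit variance. Module membership
#' `kME_gm` is the Pearson correlation of gene g with eigengene m, computed
#' for every gene against every module.
#'
#' @param expr genes x samples expression matrix.
#' @param partition a `module_partition`.
#' @return the partition with `eigengenes` (module x sample) and `kme`
#'   (gene x module) filled in.
#' @export
eigengenes_and_membership <- function(expr, partition) {
  if (ncol(expr) < 2) stop("need more than one sample", call. = FALSE)
  assignment <- partition$assignment
  mods <- setdiff(unique(assignment), "unassigned")
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  if (!length(mods)) {
    partition$eigengenes <- matrix(0, 0, ncol(expr),
                                   dimnames = list(NULL, colnames(expr)))
    partition$kme <- matrix(0, nrow(expr), 0,
                            dimnames = list(rownames(expr), NULL))
    return(partition)
  }
  eg <- t(vapply(mods, function(m) {
    module_eigengene(expr[names(assignment)[assignment == m], , drop = FALSE])
  }, numeric(ncol(expr))))
  rownames(eg) <- mods
  colnames(eg) <- colnames(expr)
  kme <- suppressWarnings(cor(t(expr), t(eg)))
  kme[is.na(kme)] <- 0
  partition$eigengenes <- eg
  partition$kme <- kme
  partition
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity `1 - cor(E_a, E_b)` while it is below
#' `merge_dissimilarity`, recomputing eigengenes after every merge, until a
#' fixed point (the conventional reading of a "correlation threshold of 0.2":
#' merge when eigengene correlation exceeds 0.8).
#'
#' @inheritParams eigengenes_and_membership
#' @param merge_dissimilarity merge cut on 1 - cor (default 0.2).
#' @return a `module_partition` with merged assignment, eigengenes and kME.
#' @export
merge_modules <- function(expr, partition, merge_dissimilarity = 0.2) {
  part <- eigengenes_and_membership(expr, partition)
  repeat {
    eg <- part$eigengenes
    if (nrow(eg) < 2) break
    d <- 1 - cor(t(eg))
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[idx[1], idx[2]] >= merge_dissimilarity) break
    a <- rownames(eg)[idx[1]]; b <- rownames(eg)[idx[2]]
    assignment <- part$assignment
    assignment[assignment == b] <- a
    # relabel by decreasing size
    mods <- setdiff(unique(assignment), "unassigned")
    sizes <- vapply(mods, function(m) sum(assignment == m), 0)
    relabel <- stats::setNames(paste0("M", seq_along(mods)),
                               mods[order(-sizes)])
    new_assignment <- ifelse(assignment == "unassigned", "unassigned",
                             relabel[assignment])
    part <- eigengenes_and_membership(
      expr, structure(list(assignment = stats::setNames(new_assignment,
                                                        names(assignment))),
                      class = "module_partition"))
  }
  part
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with a per-sample trait,
#' with the Student-t p-value on n - 2 degrees of freedom.
#'
#' @param eigengenes module x sample matrix.
#' @param trait numeric or 0/1 per-sample trait.
#' @return data.frame (module, r, p).
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  if (length(trait) != ncol(eigengenes))
    stop("trait length must equal the number of samples", call. = FALSE)
  trait <- as.numeric(trait)
  if (sd(trait) == 0) stop("trait has zero variance", call. = FALSE)
  n <- length(trait)
  rows <- lapply(rownames(eigengenes), function(m) {
    r <- cor(eigengenes[m, ], trait)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    data.frame(module = m, r = r, p = 2 * pt(-abs(tstat), df = n - 2))
  })
  do.call(rbind, rows)
}
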