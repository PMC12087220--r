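# Sequence distances (p / JC69 with pairwise gap deletion), neighbor-joining
# with a deterministic lexicographic tie-break, and patristic distances.
# NJ here is a deterministic, desk-scale stand-in for a likelihood tree; a
# user-supplied Newick tree can be fed straight into patristic().

GAP_CHARS <- c("-", ".", "N", "X", "n", "x", "?", "*")

#' Pairwise sequence distances from an alignment
#'
#' p-distance over positions where both sequences carry an unambiguous
#' residue (pairwise deletion of gaps, N/X and stops); the JC69 transform is
#' `d = -3/4 ln(1 - 4p/3)`, undefined (missing, with a warning) at
#' `p >= 3/4`.
#'
#' @param aln aligned FASTA path, an `XStringSet`, or a named character
#'   vector of equal-length sequences.
#' @param model "p" (default) or "jc69".
#' @return labelled symmetric `dist`-free matrix with zero diagonal.
#' @export
pairwise_distance <- function(aln, model = c("p", "jc69")) {
  model <- match.arg(model)
  if (is.character(aln) && length(aln) == 1 && file.exists(aln))
    aln <- Biostrings::readBStringSet(aln)
  seqs <- stats::setNames(toupper(as.character(aln)), names(aln))
  lens <- unique(nchar(seqs))
  if (length(lens) != 1)
    stop("sequences must have equal (aligned) length", call. = FALSE)
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(seqs, ""))
  valid <- !matrix(chars %in% GAP_CHARS, n, lens)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  saturated <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- valid[i, ] & valid[j, ]
      if (!any(use)) { d[i, j] <- d[j, i] <- NA_real_; next }
      p <- mean(chars[i, use] != chars[j, use])
      if (model == "jc69") {
        if (p >= 0.75) { d[i, j] <- d[j, i] <- NA_real_; saturated <- TRUE; next }
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  if (saturated)
    warning("saturated pairs (p >= 3/4) are missing under jc69",
            call. = FALSE)
  d
}

#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Standard neighbor joining on the Q criterion. When several pairs minimize
#' Q, the pair whose (sorted) representative leaf labels come first
#' lexicographically is joined, so the output is a pure function of the
#' input. Additive matrices are recovered exactly. Negative branch lengths
#' are clamped to 0 with a warning.
#'
#' @param d complete symmetric distance matrix with labels, n >= 3.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  if (anyNA(d)) stop("distance matrix has missing entries", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)

  # cluster bookkeeping: node ids are tips 1..n then internals n+1, ...
  active <- seq_len(n)              # node id per active cluster
  rep_label <- labels               # lexicographic representative per cluster
  D <- d
  next_node <- n + 1L
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  clamped <- FALSE
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    if (len < -1e-9) clamped <<- TRUE
    lens <<- c(lens, max(len, 0))
  }

  while (length(active) > 3) {
    r <- length(active)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(rep_label[ij[1]], rep_label[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    u <- next_node; next_node <- next_node + 1L
    add_edge(u, active[i], vi)
    add_edge(u, active[j], vj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    newlab <- min(rep_label[c(i, j)])
    rep_label <- c(rep_label[keep], newlab)
    active <- c(active[keep], u)
    dimnames(D) <- NULL
  }

  # final three clusters joined at one internal node (closed form)
  u <- next_node
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(u, active[1], v1)
  add_edge(u, active[2], v2)
  add_edge(u, active[3], v3)
  if (clamped)
    warning("negative branch lengths clamped to 0", call. = FALSE)

  # renumber internals to ape convention: tips 1..n, root n+1, then others
  n_internal <- next_node - n
  # internal ids appeared in creation order n+1 .. next_node; root is the last
  remap <- integer(next_node)
  remap[seq_len(n)] <- seq_len(n)
  internal_old <- (n + 1L):next_node
  # ape expects the root first among internal nodes
  ordered_internal <- c(u, setdiff(internal_old, u))
  remap[ordered_internal] <- n + seq_len(n_internal)
  tree <- list(edge = cbind(remap[edges[, 1]], remap[edges[, 2]]),
               edge.length = lens, tip.label = labels,
               Nnode = n_internal)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the unique path between every pair of leaves.
#'
#' @param tree an `ape::phylo` tree with branch lengths (e.g. from
#'   [neighbor_joining()] or read with [ape::read.tree()]).
#' @return labelled symmetric matrix with zero diagonal, rows/columns in
#'   `tree$tip.label` order.
#' @export
patristic <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}
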