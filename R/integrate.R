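# The integrative layer: barcode Jaccard similarity, physical genomic
# distance, the pairwise-matrix correlation engine (with an optional Mantel
# permutation p), GRN assembly, and centrality analysis.

#' Pairwise Jaccard similarity of regulatory barcodes
#'
#' `J(g, h) = |B_g n B_h| / |B_g u B_h|` over candidate-TF sets. Pairs where
#' both barcodes are empty are missing (with a warning); the diagonal is 1
#' for non-empty barcodes.
#'
#' @param assignment a `regulatory_assignment` from [call_candidate_tfs()],
#'   or a named list of TF id sets.
#' @return symmetric `pair_matrix` in [0, 1].
#' @export
jaccard_matrix <- function(assignment) {
  barcode <- if (inherits(assignment, "regulatory_assignment"))
    assignment$barcode else assignment
  genes <- names(barcode)
  n <- length(genes)
  j <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  empty_pair <- FALSE
  for (a in seq_len(n)) {
    for (b in a:n) {
      u <- union(barcode[[a]], barcode[[b]])
      if (!length(u)) { empty_pair <- TRUE; next }
      j[a, b] <- j[b, a] <-
        length(intersect(barcode[[a]], barcode[[b]])) / length(u)
    }
  }
  if (empty_pair)
    warning("pairs of empty barcodes have undefined Jaccard similarity",
            call. = FALSE)
  new_pair_matrix(j, "jaccard", "similarity")
}

#' Physical genomic distance between gene midpoints
#'
#' `|mid_g - mid_h|` with `mid = (start + end) / 2`, defined only for genes
#' on the same scaffold; cross-scaffold pairs are missing.
#'
#' @param annotation annotation data.frame (see [read_annotation()]).
#' @param gene_ids genes to include (default: all annotated).
#' @return symmetric `pair_matrix` of distances (zero diagonal).
#' @export
genomic_distance <- function(annotation, gene_ids = annotation$gene_id) {
  ann <- annotation[match(gene_ids, annotation$gene_id), ]
  if (anyNA(ann$gene_id))
    stop("gene ids absent from annotation: ",
         paste(setdiff(gene_ids, annotation$gene_id), collapse = ", "),
         call. = FALSE)
  bad <- ann$start > ann$end
  if (any(bad))
    stop("start > end for gene: ", paste(ann$gene_id[bad], collapse = ", "),
         call. = FALSE)
  mid <- (ann$start + ann$end) / 2
  d <- abs(outer(mid, mid, "-"))
  same <- outer(ann$scaffold, ann$scaffold, "==")
  d[!same] <- NA_real_
  dimnames(d) <- list(gene_ids, gene_ids)
  new_pair_matrix(d, "genomic_distance", "distance")
}

#' Correlate two pairwise matrices
#'
#' Pearson correlation over upper-triangle entries complete in both matrices
#' (pairwise deletion), with the parametric p-value. Because pairwise
#' entries are not independent, an optional Mantel permutation p is computed
#' by jointly permuting one matrix's rows and columns:
#' `p = (1 + #{|R_perm| >= |R_obs|}) / (1 + n_permutations)`.
#'
#' @param a,b symmetric labelled matrices sharing labels.
#' @param n_permutations Mantel permutations (default 0 = parametric only,
#'   mirroring a plain Pearson test between the matrices).
#' @param seed seed for the permutations.
#' @return list with `r`, `p`, `n_pairs`, `mantel_p` (NA if not requested),
#'   `n_permutations`.
#' @export
matrix_correlation <- function(a, b, n_permutations = 0, seed = 1) {
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) < 3)
    stop("need at least 3 shared labels", call. = FALSE)
  a <- unclass(a)[shared, shared]
  b <- unclass(b)[shared, shared]
  ut <- upper.tri(a)
  av <- a[ut]; bv <- b[ut]
  ok <- !is.na(av) & !is.na(bv)
  if (sum(ok) < 3)
    stop("fewer than 3 complete pairs", call. = FALSE)
  ct <- cor.test(av[ok], bv[ok])
  r_obs <- unname(ct$estimate)
  mantel_p <- NA_real_
  if (n_permutations > 0) {
    n <- length(shared)
    hits <- with_stream(seed, "mantel", {
      count <- 0L
      for (i in seq_len(n_permutations)) {
        perm <- sample.int(n)
        bp <- b[perm, perm][ut]
        okp <- !is.na(av) & !is.na(bp)
        if (sum(okp) < 3) next
        rp <- suppressWarnings(cor(av[okp], bp[okp]))
        if (!is.na(rp) && abs(rp) >= abs(r_obs)) count <- count + 1L
      }
      count
    })
    mantel_p <- (1 + hits) / (1 + n_permutations)
  }
  list(r = r_obs, p = ct$p.value, n_pairs = sum(ok),
       mantel_p = mantel_p, n_permutations = n_permutations)
}

#' Assemble the TF -> toxin regulatory network
#'
#' One directed edge per candidate (TF, toxin) pair, carrying the binding
#' site count and the tree-ensemble importance weight; protein-link TF-TF
#' edges are kept only when both endpoints are candidate TFs. Isolated
#' toxins are retained as nodes.
#'
#' @param assignment a `regulatory_assignment`.
#' @param ppi_edges two-column data.frame (tf1, tf2) of protein links, or a
#'   TSV path; `NULL` for none.
#' @param weights TF x target importance matrix from [importance_network()]
#'   (optional).
#' @return a `grn_graph`: list with `graph` (igraph, directed; protein links
#'   as reciprocal edge pairs flagged `kind = "ppi"`), `edges`, `nodes`.
#' @export
build_grn <- function(assignment, ppi_edges = NULL, weights = NULL) {
  stopifnot(inherits(assignment, "regulatory_assignment"))
  if (is.character(ppi_edges)) {
    lines <- readLines(ppi_edges)
    lines <- lines[nzchar(lines)]
    header <- grepl("^tf1\\s", lines[1])
    body <- if (header) lines[-1] else lines
    parts <- strsplit(body, "\t")
    bad <- which(lengths(parts) != 2)
    if (length(bad))
      stop("malformed protein-link line ", bad[1] + header, call. = FALSE)
    ppi_edges <- data.frame(tf1 = vapply(parts, `[`, "", 1),
                            tf2 = vapply(parts, `[`, "", 2))
  }
  toxins <- names(assignment$barcode)
  cand_tfs <- sort(unique(unlist(assignment$barcode)))
  edges <- assignment$hit_counts
  wt <- rep(NA_real_, nrow(edges))
  if (!is.null(weights) && nrow(edges))
    wt <- ifelse(edges$tf %in% rownames(weights) &
                   edges$gene %in% colnames(weights),
                 weights[cbind(match(edges$tf, rownames(weights)),
                               match(edges$gene, colnames(weights)))],
                 NA_real_)
  edge_df <- if (nrow(edges)) {
    data.frame(from = edges$tf, to = edges$gene, kind = "regulatory",
               tfbs_count = edges$n_hits, weight = wt)
  } else {
    data.frame(from = character(), to = character(), kind = character(),
               tfbs_count = integer(), weight = numeric())
  }
  if (!is.null(ppi_edges) && nrow(ppi_edges)) {
    keep <- ppi_edges$tf1 %in% cand_tfs & ppi_edges$tf2 %in% cand_tfs &
      ppi_edges$tf1 != ppi_edges$tf2
    pe <- ppi_edges[keep, , drop = FALSE]
    if (nrow(pe)) {
      both <- data.frame(from = c(pe$tf1, pe$tf2), to = c(pe$tf2, pe$tf1),
                         kind = "ppi", tfbs_count = NA_integer_,
                         weight = NA_real_)
      edge_df <- rbind(edge_df, both)
    }
  }
  nodes <- data.frame(name = c(cand_tfs, toxins),
                      type = c(rep("tf", length(cand_tfs)),
                               rep("toxin", length(toxins))))
  g <- igraph::graph_from_data_frame(edge_df, directed = TRUE,
                                     vertices = nodes)
  structure(list(graph = g, edges = edge_df, nodes = nodes),
            class = "grn_graph")
}

#' Node centralities of the regulatory network
#'
#' Degree bookkeeping counts directed regulatory edges in in/out degree and
#' each protein-link incidence once; total degree is their sum. Betweenness
#' counts shortest paths through each node (Brandes), treating regulatory
#' edges as directed and protein links as bidirectional, unweighted and
#' unnormalized.
#'
#' @param grn a `grn_graph` from [build_grn()].
#' @return data.frame (name, type, degree, in_degree, out_degree,
#'   betweenness).
#' @export
centralities <- function(grn) {
  stopifnot(inherits(grn, "grn_graph"))
  e <- grn$edges
  nodes <- grn$nodes$name
  reg <- e[e$kind == "regulatory", , drop = FALSE]
  ppi <- e[e$kind == "ppi", , drop = FALSE]  # reciprocal pairs
  out_deg <- stats::setNames(tabulate(factor(reg$from, nodes),
                                      length(nodes)), nodes)
  in_deg <- stats::setNames(tabulate(factor(reg$to, nodes),
                                     length(nodes)), nodes)
  und <- stats::setNames(tabulate(factor(ppi$from, nodes),
                                  length(nodes)), nodes)
  # weights = NA: hop counts, ignoring the importance edge attribute
  btw <- igraph::betweenness(grn$graph, directed = TRUE, normalized = FALSE,
                             weights = NA)
  data.frame(name = nodes, type = grn$nodes$type,
             degree = unname(out_deg + in_deg + und),
             in_degree = unname(in_deg), out_degree = unname(out_deg),
             betweenness = unname(btw[nodes]))
}
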