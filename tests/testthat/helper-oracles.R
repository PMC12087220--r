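# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct, unoptimized transcription of the defining formula
# so it shares no code path with the implementation it checks.

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# exhaustive-window PWM scan: every offset, both strands, no vectorization
oracle_scan <- function(seqs, pfm, pseudocount = 1,
                        background = rep(0.25, 4), score_fraction = 0.85,
                        both_strands = TRUE) {
  bases <- c("A", "C", "G", "T")
  counts <- pfm$counts
  prob <- sweep(counts + pseudocount * background, 2,
                colSums(counts) + pseudocount, "/")
  pwm <- log2(prob / background)
  L <- ncol(pwm)
  max_score <- sum(apply(pwm, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- list()
  for (g in names(seqs)) {
    chars <- strsplit(seqs[[g]], "")[[1]]
    if (length(chars) < L) next
    for (off in 0:(length(chars) - L)) {
      win <- chars[(off + 1):(off + L)]
      fwd <- 0
      for (j in seq_len(L)) {
        b <- match(win[j], bases)
        fwd <- fwd + if (is.na(b)) 0 else pwm[b, j]
      }
      if (fwd >= score_fraction * max_score)
        out[[length(out) + 1]] <- data.frame(
          tf = pfm$id, gene = g, offset = off, strand = "+", score = fwd)
      if (both_strands) {
        rcwin <- rev(comp[win])
        rev_s <- 0
        for (j in seq_len(L)) {
          b <- match(rcwin[j], bases)
          rev_s <- rev_s + if (is.na(b)) 0 else pwm[b, j]
        }
        if (rev_s >= score_fraction * max_score)
          out[[length(out) + 1]] <- data.frame(
            tf = pfm$id, gene = g, offset = off, strand = "-", score = rev_s)
      }
    }
  }
  if (!length(out))
    return(data.frame(tf = character(), gene = character(),
                      offset = integer(), strand = character(),
                      score = numeric()))
  do.call(rbind, out)
}

# TOM by direct triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- a[i, j]
      for (u in seq_len(n)) num <- num + a[i, u] * a[u, j]
      tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# betweenness by explicit shortest-path enumeration on a directed edge list
oracle_betweenness <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    edges$to[edges$from == v])
  btw <- stats::setNames(rep(0, length(nodes)), nodes)
  all_shortest <- function(s, t) {
    # BFS distances from s
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (dist[w] == Inf) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    if (dist[t] == Inf) return(list())
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { paths[[length(paths) + 1]] <<- path; return() }
      for (w in adj[[v]]) if (dist[w] == dist[v] + 1 && dist[w] <= dist[t])
        walk(c(path, w))
    }
    walk(s)
    Filter(function(p) p[length(p)] == t, paths)
  }
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- all_shortest(s, t)
    if (!length(paths)) next
    for (v in setdiff(nodes, c(s, t))) {
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + through / length(paths)
    }
  }
  btw
}

# random counts matrix with names
random_counts <- function(n_genes, n_cells, lambda = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  m
}

# expression matrix with two uncorrelated planted blocks + noise genes
planted_block_expr <- function(block_sizes, n_samples, n_noise = 0,
                               within_sd = 0.3, seed = 1) {
  set.seed(seed)
  rows <- list()
  truth <- integer(0)
  for (b in seq_along(block_sizes)) {
    driver <- rnorm(n_samples)
    for (i in seq_len(block_sizes[b])) {
      rows[[length(rows) + 1]] <- driver + rnorm(n_samples, 0, within_sd)
      truth <- c(truth, b)
    }
  }
  for (i in seq_len(n_noise)) {
    rows[[length(rows) + 1]] <- rnorm(n_samples)
    truth <- c(truth, 0L)
  }
  expr <- do.call(rbind, rows)
  rownames(expr) <- sprintf("g%03d", seq_len(nrow(expr)))
  colnames(expr) <- sprintf("s%03d", seq_len(n_samples))
  list(expr = expr, truth = truth)
}

# a small planted regulome without sequence simulation: `sets` is a named
# list gene -> TF ids, groups a named vector
toy_regulome <- function(sets, groups) {
  pos <- do.call(rbind, lapply(names(sets), function(g) {
    if (!length(sets[[g]])) return(NULL)
    data.frame(gene = g, tf = sets[[g]], offset = 0L, strand = "+")
  }))
  if (is.null(pos))
    pos <- data.frame(gene = character(), tf = character(),
                      offset = integer(), strand = character())
  truth_regulome(sets, pos, groups)
}

# regulome with g groups x k genes, shared + group-specific TFs, fully planted
grouped_regulome <- function(n_groups = 2, genes_per_group = 12,
                             shared = paste0("TFS", 1:2), per_group = 4) {
  sets <- list(); groups <- character()
  for (g in seq_len(n_groups)) {
    gtfs <- paste0("TFG", g, "_", seq_len(per_group))
    for (i in seq_len(genes_per_group)) {
      gene <- sprintf("TOX%02d", (g - 1) * genes_per_group + i)
      sets[[gene]] <- c(shared, gtfs)
      groups[gene] <- paste0("G", g)
    }
  }
  toy_regulome(sets, groups)
}
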