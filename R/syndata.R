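# Synthetic venom-gland generator: a tandem toxin gene family evolved on one
# pure-birth tree for both promoter and coding sequence, planted TF motif
# "barcodes" (shared + group-specific regulators), negative-binomial
# single-cell counts driven by TF activity, and gland sections with an
# anterior-posterior group gradient. Every stochastic component draws its
# randomness from a named substream of one master seed.

DNA <- c("A", "C", "G", "T")

#' Parameters for the toxin gene family simulation
#'
#' @param n_genes number of toxin paralogs (>= 2).
#' @param n_groups number of functional groups (default 3, mirroring the
#'   handful of co-regulated toxin programs a venom gland carries, e.g.
#'   neurotoxin-like / cytotoxin-like / accessory); groups are clades of the
#'   simulated tree.
#' @param birth_rate pure-birth speciation rate per unit time.
#' @param promoter_len promoter length in bases (the 500 bp upstream window).
#' @param cds_len coding sequence length in bases (rounded up to a codon).
#' @param subst_rate_promoter,subst_rate_cds substitutions/site/unit time.
#' @param shared_tfs TF identifiers planted in every lineage (present at the
#'   root).
#' @param group_tfs named list, group label -> TF id vector; these motifs can
#'   only be gained inside that group's clade.
#' @param motif_len motif width in bases.
#' @param motif_gain_prob,motif_loss_prob per-branch gain / loss probabilities
#'   of a motif.
#' @param n_scaffolds genes are laid out in tandem over at most this many
#'   scaffolds (contiguous blocks in tree order).
#' @param intergenic_gap bases of random background between consecutive genes.
#' @param ppi_prob probability that two TFs sharing a scope are linked in the
#'   synthetic protein-protein table.
#' @param seed master integer seed.
#' @return a `family_sim_params` list.
#' @export
family_sim_params <- function(n_genes, n_groups = 3, birth_rate = 1,
                              promoter_len = 500, cds_len = 300,
                              subst_rate_promoter = 0.3, subst_rate_cds = 0.3,
                              shared_tfs = paste0("TFshared", 1:2),
                              group_tfs = NULL,
                              motif_len = 10,
                              motif_gain_prob = 0.9, motif_loss_prob = 0.05,
                              n_scaffolds = 2, intergenic_gap = 2000,
                              ppi_prob = 0.4, seed = 1) {
  if (n_genes < 2) stop("n_genes must be >= 2", call. = FALSE)
  if (n_groups < 1 || n_groups > n_genes)
    stop("n_groups must be in [1, n_genes]", call. = FALSE)
  assert_prob(c(motif_gain_prob, motif_loss_prob, ppi_prob),
              "motif gain/loss and ppi probabilities")
  if (any(c(subst_rate_promoter, subst_rate_cds, birth_rate) < 0))
    stop("rates must be >= 0", call. = FALSE)
  if (is.null(group_tfs)) {
    group_tfs <- lapply(seq_len(n_groups), function(g)
      paste0("TFg", g, "_", 1:4))
    names(group_tfs) <- paste0("G", seq_len(n_groups))
  }
  cds_len <- as.integer(ceiling(cds_len / 3) * 3)
  structure(list(
    n_genes = as.integer(n_genes), n_groups = as.integer(n_groups),
    birth_rate = birth_rate, promoter_len = as.integer(promoter_len),
    cds_len = cds_len, subst_rate_promoter = subst_rate_promoter,
    subst_rate_cds = subst_rate_cds, shared_tfs = shared_tfs,
    group_tfs = group_tfs, motif_len = as.integer(motif_len),
    motif_gain_prob = motif_gain_prob, motif_loss_prob = motif_loss_prob,
    n_scaffolds = as.integer(n_scaffolds),
    intergenic_gap = as.integer(intergenic_gap),
    ppi_prob = ppi_prob, seed = as.integer(seed)),
    class = "family_sim_params")
}

#' Planted regulome truth
#'
#' @param planted_sets named list, gene -> character vector of TF ids.
#' @param motif_positions data.frame with columns gene, tf, offset (0-based
#'   within the promoter), strand.
#' @param group_of named character vector, gene -> group label.
#' @param promoter_len promoter length used to validate offsets (optional).
#' @param motif_len motif width used to validate offsets (optional).
#' @return a `truth_regulome`.
#' @export
truth_regulome <- function(planted_sets, motif_positions, group_of,
                           promoter_len = NULL, motif_len = NULL) {
  genes <- names(planted_sets)
  if (!all(genes %in% names(group_of)))
    stop("every gene must have a group", call. = FALSE)
  have <- paste(motif_positions$gene, motif_positions$tf)
  want <- unlist(lapply(genes, function(g)
    if (length(planted_sets[[g]])) paste(g, planted_sets[[g]])))
  if (!setequal(have, want %||% character()))
    stop("planted_sets and motif_positions disagree", call. = FALSE)
  if (!is.null(promoter_len) && !is.null(motif_len) &&
      nrow(motif_positions) > 0 &&
      any(motif_positions$offset < 0 |
          motif_positions$offset + motif_len > promoter_len))
    stop("a planted motif lies outside the promoter", call. = FALSE)
  structure(list(planted_sets = planted_sets,
                 motif_positions = motif_positions,
                 group_of = group_of),
            class = "truth_regulome")
}

# jukes-cantor style mutation of a base-index vector over branch length t
mutate_jc <- function(idx, rate, t) {
  p <- 0.75 * (1 - exp(-4 / 3 * rate * t))
  hit <- which(runif(length(idx)) < p)
  if (length(hit)) {
    # new base uniform among the three others
    shift <- sample.int(3L, length(hit), replace = TRUE)
    idx[hit] <- ((idx[hit] - 1L + shift) %% 4L) + 1L
  }
  idx
}

# evolve one alignment (no indels) down the tree; returns tips x sites index
# matrix in tip order
evolve_on_tree <- function(tree, len, rate) {
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  seqs <- vector("list", nnode)
  root <- n + 1L
  seqs[[root]] <- sample.int(4L, len, replace = TRUE)
  edge <- tree$edge
  # cladewise edge order is a valid preorder
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; child <- edge[e, 2]
    seqs[[child]] <- mutate_jc(seqs[[par]], rate, tree$edge.length[e])
  }
  out <- do.call(rbind, seqs[seq_len(n)])
  rownames(out) <- tree$tip.label
  out
}

idx_to_string <- function(idx) paste(DNA[idx], collapse = "")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# gain/loss two-state markov chain along branches; scope_nodes limits where
# gains may occur (the group clade); root_state applies at the root
evolve_presence <- function(tree, gain, loss, scope_nodes, root_state) {
  n <- length(tree$tip.label)
  state <- logical(n + tree$Nnode)
  state[n + 1L] <- root_state
  edge <- tree$edge
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; child <- edge[e, 2]
    if (state[par]) {
      state[child] <- runif(1) >= loss
    } else {
      state[child] <- (child %in% scope_nodes) && runif(1) < gain
    }
  }
  stats::setNames(state[seq_len(n)], tree$tip.label)
}

# all nodes (tips + internals) descending from `node`, inclusive
descendant_nodes <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  out <- node
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  for (k in kids) out <- c(out, descendant_nodes(tree, k))
  out
}

random_pfm <- function(id, motif_len, strength = 85L) {
  consensus <- sample.int(4L, motif_len, replace = TRUE)
  counts <- matrix(5L, 4, motif_len, dimnames = list(c("A", "C", "G", "T")))
  counts[cbind(consensus, seq_len(motif_len))] <- strength
  structure(list(id = id, name = id, counts = counts,
                 consensus = idx_to_string(consensus)), class = "pfm")
}

#' Simulate a co-evolving toxin gene family with planted TF barcodes
#'
#' One pure-birth tree underlies both promoter and coding-sequence evolution
#' (uniform Jukes-Cantor-style substitution, no indels, so the simulated
#' sequences are already aligned). TF motifs evolve as per-branch gain/loss
#' processes: shared TFs are present at the root, group-specific TFs can only
#' be gained inside their group's clade. At the tips, each present motif is
#' planted by overwriting the TF's consensus at a TF-specific promoter offset
#' (offsets are sampled without overlap so planted motifs never destroy each
#' other). Genes are laid out in tandem in tree traversal order so physical
#' genomic distance tracks phylogenetic distance.
#'
#' @param params a [family_sim_params()] list.
#' @return a `family_sim` list with elements `tree` (ape phylo), `promoters`,
#'   `cds`, `peptides`, `genome` (Biostrings sets), `annotation` (data.frame),
#'   `regulome` ([truth_regulome()]), `pfms`, `ppi` (data.frame), `params`.
#' @export
simulate_family <- function(params) {
  stopifnot(inherits(params, "family_sim_params"))
  p <- params
  n <- p$n_genes

  tree <- with_stream(p$seed, "tree", ape::rphylo(n, p$birth_rate, 0))
  tree <- ape::reorder.phylo(tree, "cladewise")
  # rename tips so gene numbering follows the tree traversal order
  tip_rows <- tree$edge[, 2] <= n
  dfs_tips <- tree$edge[tip_rows, 2]
  new_names <- character(n)
  new_names[dfs_tips] <- sprintf("TOX%02d", seq_len(n))
  tree$tip.label <- new_names
  genes <- sprintf("TOX%02d", seq_len(n))

  # groups = clades: cut the ultrametric tree into n_groups subtrees
  if (p$n_groups > 1) {
    cl <- cutree(hclust(as.dist(ape::cophenetic.phylo(tree)), "average"),
                 k = p$n_groups)
    # relabel groups by first appearance in gene order
    first <- order(match(unique(cl[genes]), cl[genes]))
    lab <- paste0("G", match(cl, unique(cl[genes])))
    group_of <- stats::setNames(lab[match(genes, names(cl))], genes)
  } else {
    group_of <- stats::setNames(rep("G1", n), genes)
  }
  groups <- paste0("G", seq_len(p$n_groups))

  tf_scope <- c(stats::setNames(rep("shared", length(p$shared_tfs)),
                                p$shared_tfs),
                unlist(lapply(names(p$group_tfs), function(g)
                  stats::setNames(rep(g, length(p$group_tfs[[g]])),
                                  p$group_tfs[[g]]))))
  tfs <- names(tf_scope)

  pfms <- with_stream(p$seed, "motifs", {
    lapply(stats::setNames(tfs, tfs), random_pfm, motif_len = p$motif_len)
  })
  # non-overlapping per-TF offsets and a per-TF strand
  slots <- p$promoter_len %/% p$motif_len
  if (slots < length(tfs))
    stop("promoter too short to host ", length(tfs), " motifs", call. = FALSE)
  plant <- with_stream(p$seed, "planting", {
    offs <- (sample.int(slots, length(tfs)) - 1L) * p$motif_len
    strands <- sample(c("+", "-"), length(tfs), replace = TRUE)
    list(offset = stats::setNames(offs, tfs),
         strand = stats::setNames(strands, tfs))
  })

  # presence per TF at each tip
  presence <- with_stream(p$seed, "presence", {
    out <- list()
    for (tf in tfs) {
      if (tf_scope[[tf]] == "shared") {
        scope <- seq_len(n + tree$Nnode)
        root_state <- TRUE
      } else {
        members <- genes[group_of == tf_scope[[tf]]]
        if (length(members) == 1L) {
          scope <- match(members, tree$tip.label)
        } else {
          scope <- descendant_nodes(tree, ape::getMRCA(tree, members))
        }
        root_state <- FALSE
      }
      out[[tf]] <- evolve_presence(tree, p$motif_gain_prob, p$motif_loss_prob,
                                   scope, root_state)
    }
    out
  })

  prom_idx <- with_stream(p$seed, "promoter_seq",
    evolve_on_tree(tree, p$promoter_len, p$subst_rate_promoter))
  cds_idx <- with_stream(p$seed, "cds_seq",
    evolve_on_tree(tree, p$cds_len, p$subst_rate_cds))

  # plant motifs at tips by overwriting the consensus
  positions <- list()
  planted_sets <- stats::setNames(vector("list", n), genes)
  for (g in genes) {
    present <- tfs[vapply(tfs, function(tf) isTRUE(presence[[tf]][[g]]),
                          logical(1))]
    planted_sets[[g]] <- present
    for (tf in present) {
      off <- plant$offset[[tf]]
      motif <- pfms[[tf]]$consensus
      if (plant$strand[[tf]] == "-") motif <- revcomp_chr(motif)
      midx <- match(strsplit(motif, "")[[1]], DNA)
      prom_idx[g, (off + 1L):(off + p$motif_len)] <- midx
      positions[[length(positions) + 1L]] <-
        data.frame(gene = g, tf = tf, offset = off,
                   strand = plant$strand[[tf]])
    }
  }
  motif_positions <- if (length(positions)) do.call(rbind, positions) else
    data.frame(gene = character(), tf = character(),
               offset = integer(), strand = character())
  regulome <- truth_regulome(planted_sets, motif_positions, group_of,
                             promoter_len = p$promoter_len,
                             motif_len = p$motif_len)

  promoters <- vapply(genes, function(g) idx_to_string(prom_idx[g, ]), "")
  cds <- vapply(genes, function(g) idx_to_string(cds_idx[g, ]), "")
  prom_set <- Biostrings::DNAStringSet(promoters)
  cds_set <- Biostrings::DNAStringSet(cds)
  peptides <- suppressWarnings(
    Biostrings::translate(cds_set, if.fuzzy.codon = "solve"))

  # tandem layout: contiguous blocks of genes (tree order) per scaffold
  layout <- with_stream(p$seed, "layout", {
    strands <- sample(c("+", "-"), n, replace = TRUE)
    scaf <- sort(rep_len(seq_len(p$n_scaffolds), n))
    list(strand = strands, scaffold = paste0("scaffold_", scaf))
  })
  ann <- data.frame(gene_id = genes, scaffold = layout$scaffold,
                    start = NA_integer_, end = NA_integer_,
                    strand = layout$strand, tss = NA_integer_,
                    class = "toxin", family = "3FTx",
                    group = unname(group_of[genes]))
  genome <- with_stream(p$seed, "genome_bg", {
    scafs <- list()
    for (sc in unique(ann$scaffold)) {
      pieces <- character(0)
      pos <- 0L
      for (i in which(ann$scaffold == sc)) {
        gap <- idx_to_string(sample.int(4L, p$intergenic_gap, replace = TRUE))
        pieces <- c(pieces, gap)
        pos <- pos + p$intergenic_gap
        if (ann$strand[i] == "+") {
          pieces <- c(pieces, promoters[i], cds[i])
          ann$start[i] <- pos + p$promoter_len + 1L
          ann$end[i] <- pos + p$promoter_len + p$cds_len
          ann$tss[i] <- ann$start[i]
          pos <- pos + p$promoter_len + p$cds_len
        } else {
          pieces <- c(pieces, revcomp_chr(cds[i]), revcomp_chr(promoters[i]))
          ann$start[i] <- pos + 1L
          ann$end[i] <- pos + p$cds_len
          ann$tss[i] <- ann$end[i]
          pos <- pos + p$cds_len + p$promoter_len
        }
      }
      pieces <- c(pieces,
                  idx_to_string(sample.int(4L, p$intergenic_gap,
                                           replace = TRUE)))
      scafs[[sc]] <- paste(pieces, collapse = "")
    }
    Biostrings::DNAStringSet(unlist(scafs))
  })

  # synthetic protein-protein links among TFs sharing a scope
  ppi <- with_stream(p$seed, "ppi", {
    out <- list()
    if (length(tfs) >= 2) {
      pairs <- utils::combn(tfs, 2)
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        same <- tf_scope[[a]] == tf_scope[[b]] ||
          tf_scope[[a]] == "shared" || tf_scope[[b]] == "shared"
        if (same && runif(1) < p$ppi_prob)
          out[[length(out) + 1L]] <- data.frame(tf1 = a, tf2 = b)
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(tf1 = character(), tf2 = character())
  })

  structure(list(tree = tree, promoters = prom_set, cds = cds_set,
                 peptides = peptides, genome = genome, annotation = ann,
                 regulome = regulome, pfms = pfms, ppi = ppi,
                 tf_scope = tf_scope, params = p),
            class = "family_sim")
}

#' Parameters for the single-cell count simulation
#'
#' @param n_cells number of cells.
#' @param populations list of populations, each a list with `name`, `fraction`
#'   (fractions sum to 1), `group_weights` (named vector over toxin groups,
#'   the TF-activity level for that group's regulators in this population),
#'   and `markers` (logical: does this population express the epithelial
#'   markers). `NULL` builds the default: one secretory population per group
#'   (0.6 total) plus a non-secretory rest.
#' @param depth_mean mean per-cell sequencing depth (reads/cell; depths are
#'   log-normal around this mean).
#' @param nb_dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2).
#' @param tf_activity_noise sd of the mean-preserving log-normal per-cell
#'   noise on TF activity (populations with zero base activity stay silent).
#' @param leak_rate baseline expression fraction for unregulated genes.
#' @param marker_genes epithelial marker gene ids.
#' @param n_background number of unregulated background genes.
#' @param seed master integer seed.
#' @export
cell_sim_params <- function(n_cells = 800, populations = NULL,
                            depth_mean = 5000, nb_dispersion = 0.1,
                            tf_activity_noise = 0.15, leak_rate = 0.01,
                            marker_genes = c("LAMA3", "EPCAM"),
                            n_background = 100, seed = 1) {
  if (depth_mean <= 0) stop("depth_mean must be > 0", call. = FALSE)
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  assert_prob(leak_rate, "leak_rate")
  if (!is.null(populations)) {
    if (!length(populations))
      stop("populations list must be non-empty", call. = FALSE)
    fr <- vapply(populations, `[[`, 0, "fraction")
    if (abs(sum(fr) - 1) > 1e-8)
      stop("population fractions must sum to 1", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), populations = populations,
                 depth_mean = depth_mean, nb_dispersion = nb_dispersion,
                 tf_activity_noise = tf_activity_noise,
                 leak_rate = leak_rate, marker_genes = marker_genes,
                 n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "cell_sim_params")
}

default_populations <- function(groups) {
  pops <- lapply(seq_along(groups), function(i) {
    w <- stats::setNames(rep(0.02, length(groups)), groups)
    w[groups[i]] <- 1
    list(name = paste0("secretory_", groups[i]),
         fraction = 0.6 / length(groups), group_weights = w, markers = TRUE)
  })
  c(pops, list(list(name = "non_secretory", fraction = 0.4,
                    group_weights = stats::setNames(rep(0, length(groups)),
                                                    groups),
                    markers = FALSE)))
}

#' Simulate population-structured single-cell toxin counts
#'
#' Counts are negative-binomial with log-normal per-cell depths. A toxin's
#' mean in a cell is `depth * gene_weight * (leak_rate + summed TF activity)`
#' over its planted TFs; TF transcripts co-vary with their activities, so the
#' regulatory signal is recoverable from expression alone. A matched bulk
#' library (negative binomial around the expected pseudo-bulk) is returned for
#' the divergence comparison.
#'
#' @param regulome a [truth_regulome()].
#' @param params a [cell_sim_params()].
#' @return list with `counts` (genes x cells integer matrix), `cell_labels`
#'   (population per cell), `tf_activity` (TF x cell matrix), `bulk` (named
#'   count vector), `gene_info` (gene_id, class), `params`.
#' @export
simulate_cells <- function(regulome, params) {
  stopifnot(inherits(regulome, "truth_regulome"),
            inherits(params, "cell_sim_params"))
  p <- params
  toxins <- names(regulome$planted_sets)
  groups <- unique(unname(regulome$group_of[toxins]))
  tfs <- sort(unique(unlist(regulome$planted_sets)))
  pops <- p$populations %||% default_populations(groups)
  if (!length(pops)) stop("populations list must be non-empty", call. = FALSE)
  pop_groups <- unique(unlist(lapply(pops, function(x) names(x$group_weights))))
  if (!all(groups %in% pop_groups))
    stop("populations must provide weights for every toxin group",
         call. = FALSE)

  # scope of each TF = the groups of the genes it regulates
  tf_groups <- lapply(stats::setNames(tfs, tfs), function(tf) {
    unique(unname(regulome$group_of[
      toxins[vapply(regulome$planted_sets[toxins],
                    function(s) tf %in% s, logical(1))]]))
  })

  bg <- if (p$n_background > 0) sprintf("BG%03d", seq_len(p$n_background))
        else character()
  genes <- c(toxins, tfs, p$marker_genes, bg)
  gene_info <- data.frame(
    gene_id = genes,
    class = c(rep("toxin", length(toxins)), rep("tf", length(tfs)),
              rep("marker", length(p$marker_genes)),
              rep("other", length(bg))))

  w_toxin <- 0.5 / max(length(toxins), 1)
  w_tf <- 0.1 / max(length(tfs), 1)
  w_marker <- 0.02 / max(length(p$marker_genes), 1)

  with_stream(p$seed, "cells", {
    bg_base <- if (length(bg))
      stats::setNames(rlnorm(length(bg), log(0.35 / length(bg)), 0.5), bg)
    else stats::setNames(numeric(0), character(0))

    nc <- p$n_cells
    cells <- if (nc > 0) sprintf("cell%04d", seq_len(nc)) else character()
    if (nc == 0) {
      counts <- matrix(0L, length(genes), 0,
                       dimnames = list(genes, character()))
      mu <- matrix(0, length(genes), 0, dimnames = list(genes, character()))
      labels <- stats::setNames(character(0), character(0))
      act <- matrix(0, length(tfs), 0, dimnames = list(tfs, character()))
    } else {
      fr <- vapply(pops, `[[`, 0, "fraction")
      labels <- stats::setNames(
        sample(vapply(pops, `[[`, "", "name"), nc, replace = TRUE, prob = fr),
        cells)
      depth <- rlnorm(nc, log(p$depth_mean) - 0.3^2 / 2, 0.3)
      pop_of <- match(labels, vapply(pops, `[[`, "", "name"))

      act <- matrix(0, length(tfs), nc, dimnames = list(tfs, cells))
      for (i in seq_along(tfs)) {
        base <- vapply(pop_of, function(j) {
          w <- pops[[j]]$group_weights
          max(w[intersect(tf_groups[[i]], names(w))], 0)
        }, 0)
        # mean-preserving log-normal noise: silent populations stay silent
        act[i, ] <- base * exp(rnorm(nc, 0, p$tf_activity_noise) -
                                 p$tf_activity_noise^2 / 2)
      }

      mu <- matrix(0, length(genes), nc, dimnames = list(genes, cells))
      for (g in toxins) {
        set <- regulome$planted_sets[[g]]
        drive <- if (length(set)) colSums(act[set, , drop = FALSE]) else 0
        mu[g, ] <- depth * w_toxin * (p$leak_rate + drive)
      }
      for (tf in tfs)
        mu[tf, ] <- depth * w_tf * (p$leak_rate + act[tf, ])
      marker_on <- vapply(pop_of, function(j) isTRUE(pops[[j]]$markers),
                          logical(1))
      for (m in p$marker_genes)
        mu[m, ] <- depth * w_marker * ifelse(marker_on, 1, p$leak_rate)
      for (g in bg)
        mu[g, ] <- depth * bg_base[[g]]

      counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / p$nb_dispersion),
                       nrow(mu), ncol(mu), dimnames = dimnames(mu))
    }

    bulk_mu <- if (nc > 0) rowSums(mu) else
      stats::setNames(rep(0, length(genes)), genes)
    bulk <- stats::setNames(
      rnbinom(length(bulk_mu), mu = bulk_mu, size = 10 / p$nb_dispersion),
      genes)

    list(counts = counts, cell_labels = labels, tf_activity = act,
         bulk = bulk, gene_info = gene_info, params = p)
  })
}

#' Parameters for the gland-section image simulation
#'
#' @param grid_shape integer (rows, cols) of the section grid.
#' @param mask logical grid of in-gland pixels; `NULL` uses an inscribed
#'   ellipse.
#' @param axis which grid dimension runs anterior -> posterior ("col" or
#'   "row"); anterior is index 1.
#' @param group_gradient named vector, group -> mean axis position in [0, 1].
#'   `NULL` spreads groups evenly over [0.2, 0.8].
#' @param gradient_sd spread of each group's Gaussian axis profile
#'   (normalized axis units).
#' @param noise_sd sd of additive per-pixel intensity noise.
#' @param seed master integer seed.
#' @export
section_sim_params <- function(grid_shape = c(40, 60), mask = NULL,
                               axis = c("col", "row"),
                               group_gradient = NULL, gradient_sd = 0.15,
                               noise_sd = 0.05, seed = 1) {
  axis <- match.arg(axis)
  if (is.null(mask)) {
    r <- grid_shape[1]; cc <- grid_shape[2]
    y <- (row(matrix(0, r, cc)) - (r + 1) / 2) / (r / 2)
    x <- (col(matrix(0, r, cc)) - (cc + 1) / 2) / (cc / 2)
    mask <- (x^2 + y^2) <= 1
  }
  if (!any(mask)) stop("mask must contain at least one pixel", call. = FALSE)
  if (!is.null(group_gradient) &&
      (any(group_gradient < 0) || any(group_gradient > 1)))
    stop("gradient means must lie in [0, 1]", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape), mask = mask,
                 axis = axis, group_gradient = group_gradient,
                 gradient_sd = gradient_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "section_sim_params")
}

#' An ion-image stack
#'
#' @param images named list of equally shaped non-negative intensity matrices,
#'   one per toxin.
#' @param mask logical matrix of in-gland pixels.
#' @param axis_dim anterior -> posterior dimension ("col" or "row").
#' @param reverse logical; `TRUE` if the axis runs posterior -> anterior.
#' @export
ion_image_stack <- function(images, mask, axis_dim = c("col", "row"),
                            reverse = FALSE) {
  axis_dim <- match.arg(axis_dim)
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1 || !identical(dims[[1]], dim(mask)))
    stop("all grids and the mask must share one shape", call. = FALSE)
  structure(list(images = images, mask = mask,
                 axis = list(dim = axis_dim, reverse = reverse)),
            class = "ion_image_stack")
}

#' Simulate gland sections with an anterior-posterior group gradient
#'
#' Each toxin's intensity is a masked Gaussian profile along the gland axis,
#' centered at its group's gradient position, plus truncated Gaussian pixel
#' noise; intensity is exactly 0 outside the mask.
#'
#' @param regulome a [truth_regulome()] (supplies gene -> group).
#' @param params a [section_sim_params()].
#' @return an [ion_image_stack()].
#' @export
simulate_sections <- function(regulome, params) {
  stopifnot(inherits(regulome, "truth_regulome"),
            inherits(params, "section_sim_params"))
  p <- params
  toxins <- names(regulome$planted_sets)
  groups <- unique(unname(regulome$group_of[toxins]))
  grad <- p$group_gradient
  if (is.null(grad)) {
    grad <- stats::setNames(
      if (length(groups) == 1) 0.5 else
        seq(0.2, 0.8, length.out = length(groups)), groups)
  }
  if (!all(groups %in% names(grad)))
    stop("group_gradient must cover every group", call. = FALSE)
  r <- p$grid_shape[1]; cc <- p$grid_shape[2]
  coord <- if (p$axis == "col") {
    matrix(rep((seq_len(cc) - 1) / max(cc - 1, 1), each = r), r, cc)
  } else {
    matrix(rep((seq_len(r) - 1) / max(r - 1, 1), cc), r, cc)
  }
  with_stream(p$seed, "sections", {
    images <- lapply(stats::setNames(toxins, toxins), function(g) {
      mu <- grad[[regulome$group_of[[g]]]]
      base <- exp(-(coord - mu)^2 / (2 * p$gradient_sd^2))
      img <- base + matrix(rnorm(r * cc, 0, p$noise_sd), r, cc)
      img <- pmax(img, 0)
      img[!p$mask] <- 0
      img
    })
    ion_image_stack(images, p$mask, axis_dim = p$axis)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits FASTA (genome, promoters, CDS, peptides), the annotation TSV, the
#' Newick tree, JASPAR-style motif records, MatrixMarket counts with name
#' files, the bulk count TSV, truth tables (cell labels, planted barcode,
#' TF activity), the protein-link TSV, and per-toxin intensity grids plus
#' mask under `images/`. All files round-trip through the package's readers.
#'
#' @param family a [simulate_family()] result.
#' @param cells a [simulate_cells()] result (optional).
#' @param sections an [ion_image_stack()] (optional).
#' @param dir output directory.
#' @return invisibly, a named vector of written paths.
#' @export
write_fixture <- function(family, cells = NULL, sections = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  wr <- function(name, fun) {
    path <- file.path(dir, name)
    fun(path)
    paths[[name]] <<- path
  }
  wr("genome.fasta", function(f)
    Biostrings::writeXStringSet(family$genome, f))
  wr("promoters.fasta", function(f)
    Biostrings::writeXStringSet(family$promoters, f))
  wr("cds.fasta", function(f) Biostrings::writeXStringSet(family$cds, f))
  wr("peptides.fasta", function(f)
    Biostrings::writeXStringSet(family$peptides, f))
  wr("annotation.tsv", function(f) write_annotation(family$annotation, f))
  wr("tree.nwk", function(f) ape::write.tree(family$tree, f))
  wr("motifs.txt", function(f) write_pfms(family$pfms, f))
  wr("ppi.tsv", function(f)
    write.table(family$ppi, f, sep = "\t", quote = FALSE, row.names = FALSE))
  wr("truth_barcode.tsv", function(f)
    write.table(family$regulome$motif_positions, f, sep = "\t",
                quote = FALSE, row.names = FALSE))
  wr("truth_groups.tsv", function(f)
    write.table(data.frame(gene_id = names(family$regulome$group_of),
                           group = unname(family$regulome$group_of)),
                f, sep = "\t", quote = FALSE, row.names = FALSE))
  if (!is.null(cells)) {
    write_counts_mtx(cells$counts, dir)
    paths[["counts.mtx"]] <- file.path(dir, "counts.mtx")
    wr("bulk.tsv", function(f)
      write.table(data.frame(gene_id = names(cells$bulk),
                             count = unname(cells$bulk)),
                  f, sep = "\t", quote = FALSE, row.names = FALSE))
    wr("cell_labels.tsv", function(f)
      write.table(data.frame(cell_id = names(cells$cell_labels),
                             population = unname(cells$cell_labels)),
                  f, sep = "\t", quote = FALSE, row.names = FALSE))
    wr("gene_info.tsv", function(f)
      write.table(cells$gene_info, f, sep = "\t", quote = FALSE,
                  row.names = FALSE))
    wr("tf_activity.tsv", function(f) write_matrix_tsv(cells$tf_activity, f))
  }
  if (!is.null(sections)) {
    img_dir <- file.path(dir, "images")
    if (!dir.exists(img_dir)) dir.create(img_dir)
    for (g in names(sections$images))
      write_grid_tsv(sections$images[[g]], file.path(img_dir, paste0(g, ".tsv")))
    write_grid_tsv(sections$mask * 1, file.path(img_dir, "mask.tsv"))
    writeLines(sections$axis$dim, file.path(img_dir, "axis.txt"))
    paths[["images"]] <- img_dir
  }
  invisible(unlist(paths))
}

#' Simulate and write a complete venom-gland fixture
#'
#' Convenience wrapper composing [simulate_family()], [simulate_cells()] and
#' [simulate_sections()] under one master seed, optionally writing the file
#' set with [write_fixture()].
#'
#' @param dir output directory, or `NULL` to keep everything in memory.
#' @param seed master seed.
#' @param n_genes,n_cells family and cell sizes.
#' @param ... further arguments passed to [family_sim_params()].
#' @return list with `family`, `cells`, `sections` (and `dir` if written).
#' @export
simulate_venom_fixture <- function(dir = NULL, seed = 1, n_genes = 24,
                                   n_cells = 600, ...) {
  fam <- simulate_family(family_sim_params(n_genes = n_genes, seed = seed, ...))
  cells <- simulate_cells(fam$regulome,
                          cell_sim_params(n_cells = n_cells,
                                          seed = substream_seed(seed, "cells")))
  sections <- simulate_sections(
    fam$regulome,
    section_sim_params(seed = substream_seed(seed, "sections")))
  if (!is.null(dir)) write_fixture(fam, cells, sections, dir)
  list(family = fam, cells = cells, sections = sections, dir = dir)
}
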