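# Promoter extraction, PWM motif scanning, candidate-TF ("barcode") calling,
# and tree-ensemble TF -> gene importance weights.

#' Extract TSS-anchored promoters from a genome
#'
#' For a + strand gene the promoter is the genomic span
#' `[tss - promoter_len, tss - 1]` (1-based inclusive); for a - strand gene
#' it is the reverse complement of `[tss + 1, tss + promoter_len]`. Spans are
#' clamped at scaffold boundaries with a warning.
#'
#' @param genome a named `DNAStringSet` or FASTA path.
#' @param annotation annotation data.frame (see [read_annotation()]).
#' @param promoter_len bases upstream of the TSS (default 500).
#' @return a `promoter_set`: list with `seq` (named `DNAStringSet`) and
#'   `coords` (gene_id, scaffold, start, end, strand).
#' @export
extract_promoters <- function(genome, annotation, promoter_len = 500) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- character(nrow(annotation))
  coords <- annotation[, c("gene_id", "scaffold", "strand")]
  coords$start <- NA_integer_; coords$end <- NA_integer_
  clamped <- character(0)
  for (i in seq_len(nrow(annotation))) {
    gene <- annotation$gene_id[i]
    sc <- annotation$scaffold[i]
    if (!sc %in% names(genome))
      stop("scaffold '", sc, "' of gene ", gene, " not in genome",
           call. = FALSE)
    slen <- Biostrings::width(genome[sc])
    tss <- annotation$tss[i]
    if (is.na(tss) || tss < 1 || tss > slen)
      stop("TSS of gene ", gene, " lies outside its scaffold", call. = FALSE)
    strand <- annotation$strand[i]
    if (!strand %in% c("+", "-"))
      stop("gene ", gene, " has strand '", strand, "'", call. = FALSE)
    if (strand == "+") {
      from <- tss - promoter_len; to <- tss - 1
      if (from < 1) { from <- 1; clamped <- c(clamped, gene) }
      if (to < from) { seqs[i] <- ""; next }
      s <- Biostrings::subseq(genome[[sc]], from, to)
    } else {
      from <- tss + 1; to <- tss + promoter_len
      if (to > slen) { to <- slen; clamped <- c(clamped, gene) }
      if (to < from) { seqs[i] <- ""; next }
      s <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[sc]], from, to))
    }
    seqs[i] <- as.character(s)
    coords$start[i] <- from; coords$end[i] <- to
  }
  if (length(clamped))
    warning("promoters clamped at scaffold boundaries: ",
            paste(clamped, collapse = ", "), call. = FALSE)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- annotation$gene_id
  structure(list(seq = out, coords = coords), class = "promoter_set")
}

pfm_to_pwm <- function(pfm, pseudocount = 1, background = rep(0.25, 4)) {
  counts <- pfm$counts
  tot <- colSums(counts)
  prob <- sweep(counts + pseudocount * background, 2, tot + pseudocount, "/")
  log2(prob / background)
}

score_windows <- function(pwm, seq_idx) {
  L <- ncol(pwm)
  n <- length(seq_idx) - L + 1
  if (n < 1) return(numeric(0))
  scores <- numeric(n)
  for (j in seq_len(L)) {
    b <- seq_idx[j:(j + n - 1)]
    s <- ifelse(is.na(b), 0, pwm[cbind(pmax(b, 1L), j)])
    s[is.na(b)] <- 0   # N scores 0 at that position
    scores <- scores + s
  }
  scores
}

revcomp_pwm <- function(pwm) {
  out <- pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

#' Scan promoters with position weight matrices
#'
#' PFMs are converted to log2-odds PWMs,
#' `PWM_bi = log2((count_bi + pc * bg_b) / (sum_b count_bi + pc) / bg_b)`;
#' positions holding N contribute 0. Every window (both strands if requested)
#' scoring at least `score_fraction` of the maximum attainable score of that
#' motif is reported. Overlapping hits are all kept.
#'
#' @param promoters a `promoter_set` from [extract_promoters()], a named
#'   `DNAStringSet`, or a named character vector.
#' @param pfms list of `pfm` objects (see [read_pfms()]).
#' @param pseudocount PWM pseudocount, distributed by background (default 1).
#' @param background base frequencies A,C,G,T (default uniform).
#' @param score_fraction fraction of the maximum attainable score required
#'   for a hit (default 0.85, i.e. a deficit of 0.15).
#' @param both_strands scan the reverse strand as well (default TRUE).
#' @return data.frame (tf, gene, offset [0-based], strand, score).
#' @export
pwm_scan <- function(promoters, pfms, pseudocount = 1,
                     background = rep(0.25, 4), score_fraction = 0.85,
                     both_strands = TRUE) {
  if (inherits(promoters, "promoter_set")) promoters <- promoters$seq
  seqs <- stats::setNames(as.character(promoters), names(promoters))
  if (abs(sum(background) - 1) > 1e-8)
    stop("background must sum to 1", call. = FALSE)
  if (score_fraction <= 0 || score_fraction > 1)
    stop("score_fraction must lie in (0, 1]", call. = FALSE)
  hits <- list()
  skipped <- character(0)
  for (pfm in pfms) {
    pwm <- pfm_to_pwm(pfm, pseudocount, background)
    max_score <- sum(apply(pwm, 2, max))
    thr <- score_fraction * max_score
    pwms <- list(`+` = pwm)
    if (both_strands) pwms$`-` <- revcomp_pwm(pwm)
    for (g in names(seqs)) {
      idx <- match(strsplit(seqs[[g]], "")[[1]], DNA)
      if (length(idx) < ncol(pwm)) {
        skipped <- c(skipped, paste0(pfm$id, "/", g))
        next
      }
      for (strand in names(pwms)) {
        sc <- score_windows(pwms[[strand]], idx)
        pass <- which(sc >= thr)
        if (length(pass))
          hits[[length(hits) + 1L]] <- data.frame(
            tf = pfm$id, gene = g, offset = pass - 1L, strand = strand,
            score = sc[pass])
      }
    }
  }
  if (length(skipped))
    warning("motif longer than promoter, skipped: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  if (!length(hits))
    return(data.frame(tf = character(), gene = character(),
                      offset = integer(), strand = character(),
                      score = numeric()))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Call candidate TFs per toxin gene (the regulatory barcode)
#'
#' A (TF, toxin) pair is a candidate iff the TF belongs to the toxin-module
#' TF set AND has at least one binding site in that toxin's promoter. The
#' candidate set per toxin is its barcode.
#'
#' @param module_tf_ids TFs co-expressed in the toxin modules.
#' @param hits scan hits from [pwm_scan()].
#' @param toxin_ids toxin gene identifiers.
#' @return a `regulatory_assignment`: list with `barcode` (named list,
#'   toxin -> TF id vector), `hit_counts` (data.frame gene, tf, n_hits) and
#'   `weights` (NULL until [importance_network()] supplies them).
#' @export
call_candidate_tfs <- function(module_tf_ids, hits, toxin_ids) {
  if (!length(module_tf_ids)) {
    warning("empty module TF set: no candidates", call. = FALSE)
    return(structure(list(
      barcode = stats::setNames(rep(list(character()), length(toxin_ids)),
                                toxin_ids),
      hit_counts = data.frame(gene = character(), tf = character(),
                              n_hits = integer()),
      weights = NULL), class = "regulatory_assignment"))
  }
  sel <- hits[hits$tf %in% module_tf_ids & hits$gene %in% toxin_ids, ,
              drop = FALSE]
  counts <- if (nrow(sel)) {
    agg <- stats::aggregate(list(n_hits = sel$score), list(gene = sel$gene,
                                                           tf = sel$tf),
                            FUN = length)
    agg[order(agg$gene, agg$tf), ]
  } else {
    data.frame(gene = character(), tf = character(), n_hits = integer())
  }
  barcode <- lapply(stats::setNames(toxin_ids, toxin_ids), function(g)
    sort(unique(counts$tf[counts$gene == g])))
  structure(list(barcode = barcode, hit_counts = counts, weights = NULL),
            class = "regulatory_assignment")
}

#' TF -> target importance weights from a randomized tree ensemble
#'
#' Per target gene, fits an ensemble of randomized regression trees with TF
#' expression as predictors (candidate features per split = sqrt of the
#' number of TFs, bootstrap resampling per tree); a TF's importance is the
#' total variance reduction attributed to its splits, normalized to sum 1
#' per target when any split occurred. Deterministic given the seed.
#'
#' @param expr genes x samples expression matrix (e.g. log1p-CPM).
#' @param tf_ids predictor (TF) gene ids.
#' @param target_ids target (toxin) gene ids; a target present among the TFs
#'   is excluded from its own predictor set.
#' @param n_trees trees per target (default 1000).
#' @param min_node minimal node size to attempt a split (default 5).
#' @param seed integer seed.
#' @return TF x target importance matrix (columns sum to 1 or 0).
#' @export
importance_network <- function(expr, tf_ids, target_ids, n_trees = 1000,
                               min_node = 5, seed = 1) {
  if (ncol(expr) < 10) stop("need at least 10 samples", call. = FALSE)
  missing <- setdiff(c(tf_ids, target_ids), rownames(expr))
  if (length(missing))
    stop("ids absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  w <- matrix(0, length(tf_ids), length(target_ids),
              dimnames = list(tf_ids, target_ids))
  for (j in seq_along(target_ids)) {
    tgt <- target_ids[j]
    preds <- setdiff(tf_ids, tgt)
    x <- t(expr[preds, , drop = FALSE])
    y <- as.numeric(expr[tgt, ])
    if (sd(y) == 0 || !length(preds)) next
    mtry <- max(1L, floor(sqrt(length(preds))))
    imp <- rf_importance_cpp(x, y, as.integer(n_trees), as.integer(mtry),
                             as.integer(min_node),
                             substream_seed(seed, paste0("rf_", tgt)))
    if (sum(imp) > 0) imp <- imp / sum(imp)
    w[preds, j] <- imp
  }
  w
}
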