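random_genome <- function(len, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

test_that("promoter extraction follows the TSS/strand coordinate convention", {
  g <- Biostrings::DNAStringSet(c(s = random_genome(2000, 1)))
  ann <- data.frame(gene_id = c("plus", "minus", "clamped"),
                    scaffold = "s", start = c(1000, 500, 300),
                    end = c(1200, 700, 400),
                    strand = c("+", "-", "+"),
                    tss = c(1000, 700, 300),
                    class = "toxin", family = "f", group = "G1")
  expect_warning(ps <- extract_promoters(g, ann), "clamped")
  gs <- as.character(g[["s"]])
  # + strand: genomic span [tss-500, tss-1]
  expect_identical(as.character(ps$seq[["plus"]]), substr(gs, 500, 999))
  expect_equal(ps$coords$start[1], 500)
  expect_equal(ps$coords$end[1], 999)
  # - strand: reverse complement of [tss+1, tss+500]
  want <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gs, 701, 1200))))
  expect_identical(as.character(ps$seq[["minus"]]), want)
  # clamp at the scaffold start: span 1..299 of length 299
  expect_identical(nchar(as.character(ps$seq[["clamped"]])), 299L)
  expect_equal(ps$coords$start[3], 1)
  bad <- ann[1, ]; bad$tss <- 5000
  expect_error(extract_promoters(g, bad), "outside")
})

test_that("motif records parse, reject malformed input, and round-trip", {
  path <- tempfile(fileext = ".txt")
  writeLines(c(">M1 FOXA1", "A [ 1 2 3 ]", "C [ 4 0 1 ]", "G [ 2 2 2 ]",
               "T [ 3 6 4 ]",
               ">M2 KLF5", "10 0", "0 10", "0 0", "0 0"), path)
  pfms <- read_pfms(path)
  expect_length(pfms, 2L)
  expect_identical(ncol(pfms[["M1"]]$counts), 3L)
  expect_identical(ncol(pfms[["M2"]]$counts), 2L)
  expect_identical(pfms[["M1"]]$name, "FOXA1")
  expect_equal(unname(pfms[["M2"]]$counts["C", 2]), 10)
  out <- tempfile(fileext = ".txt")
  write_pfms(pfms, out)
  again <- read_pfms(out)
  expect_equal(lapply(again, `[[`, "counts"), lapply(pfms, `[[`, "counts"))
  writeLines(c(">bad x", "1 2", "3 4", "5 6"), path)
  expect_error(read_pfms(path), "bad")
})

test_that("PWM scanning finds exact consensus hits with the stated score", {
  set.seed(2)
  pfm <- structure(list(id = "TF1", name = "TF1",
                        counts = matrix(c(97, 1, 1, 1), 4, 8,
                                        dimnames = list(c("A", "C", "G", "T")))[
                          , 1:8]), class = "pfm")
  # consensus AAAAAAAA embedded at offset 50 in a C/G background
  bg <- paste(sample(c("C", "G"), 200, replace = TRUE), collapse = "")
  seq <- paste0(substr(bg, 1, 50), "AAAAAAAA", substr(bg, 59, 200))
  hits <- pwm_scan(c(gene1 = seq), list(pfm), score_fraction = 1,
                   both_strands = FALSE)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$offset, 50L)
  pwm <- log2(((pfm$counts + 0.25) / (100 + 1)) / 0.25)
  expect_equal(hits$score, sum(apply(pwm, 2, max)), tolerance = 1e-12)
  # embedded reverse complement found on the minus strand with equal score
  seq_rc <- paste0(substr(bg, 1, 50), "TTTTTTTT", substr(bg, 59, 200))
  hits_rc <- pwm_scan(c(gene1 = seq_rc), list(pfm), score_fraction = 1)
  expect_identical(hits_rc$strand, "-")
  expect_identical(hits_rc$offset, 50L)
  expect_equal(hits_rc$score, sum(apply(pwm, 2, max)), tolerance = 1e-12)
  # a motif longer than the promoter is skipped with a warning
  expect_warning(none <- pwm_scan(c(tiny = "ACGT"), list(pfm)), "skipped")
  expect_identical(nrow(none), 0L)
})

test_that("scanner agrees with the exhaustive-window oracle", {
  set.seed(11)
  for (rep in 1:6) {
    pfm <- structure(list(id = "TFX", name = "TFX",
                          counts = matrix(sample(0:20, 4 * 7, TRUE), 4, 7,
                                          dimnames = list(c("A", "C", "G",
                                                            "T")))),
                     class = "pfm")
    pfm$counts[, colSums(pfm$counts) == 0] <- 1
    seqs <- stats::setNames(
      vapply(1:4, function(i) random_genome(150, 100 * rep + i), ""),
      paste0("g", 1:4))
    # include an N to exercise the zero-score rule
    substr(seqs[1], 10, 10) <- "N"
    got <- pwm_scan(seqs, list(pfm), score_fraction = 0.8)
    want <- oracle_scan(seqs, pfm, score_fraction = 0.8)
    key <- function(d) sort(paste(d$gene, d$offset, d$strand,
                                  round(d$score, 9)))
    expect_identical(key(got), key(want))
  }
})

test_that("promoter extraction and scanning are strand-consistent", {
  # scanning the - strand promoter for M equals scanning the + span for
  # revcomp(M)
  g <- Biostrings::DNAStringSet(c(s = random_genome(1500, 5)))
  ann <- data.frame(gene_id = "m", scaffold = "s", start = 100, end = 400,
                    strand = "-", tss = 400, class = "toxin",
                    family = "f", group = "G1")
  ps <- extract_promoters(g, ann)
  pfm <- structure(list(id = "T", name = "T",
                        counts = matrix(sample(0:9, 24, TRUE) + 1, 4, 6,
                                        dimnames = list(c("A", "C", "G",
                                                          "T")))),
                   class = "pfm")
  plus_span <- substr(as.character(g[["s"]]), 401, 900)
  rc_pfm <- pfm
  rc_pfm$counts <- pfm$counts[4:1, 6:1]
  rownames(rc_pfm$counts) <- c("A", "C", "G", "T")
  h1 <- pwm_scan(stats::setNames(as.character(ps$seq), "m"), list(pfm),
                 score_fraction = 0.75, both_strands = TRUE)
  h2 <- pwm_scan(c(m = plus_span), list(rc_pfm), score_fraction = 0.75,
                 both_strands = TRUE)
  expect_identical(nrow(h1), nrow(h2))
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
})

test_that("candidate-TF calling applies the module and binding-site rules", {
  hits <- data.frame(tf = c("TF1", "TF1", "TF2", "TF3"),
                     gene = c("TOXA", "TOXA", "TOXA", "OTHER"),
                     offset = c(1L, 30L, 2L, 3L),
                     strand = "+", score = 10)
  asg <- call_candidate_tfs(c("TF1", "TF3", "TF4"), hits, c("TOXA", "TOXB"))
  # module TF with 2 hits is a candidate carrying that count
  expect_identical(asg$barcode$TOXA, "TF1")
  expect_identical(asg$hit_counts$n_hits[asg$hit_counts$tf == "TF1"], 2L)
  # TF2 binds but is not in a toxin module; TF3 binds no toxin; TF4 no hits
  expect_false("TF2" %in% unlist(asg$barcode))
  expect_false("TF3" %in% unlist(asg$barcode))
  expect_false("TF4" %in% unlist(asg$barcode))
  expect_identical(asg$barcode$TOXB, character(0))
  expect_warning(empty <- call_candidate_tfs(character(), hits, "TOXA"),
                 "empty")
  expect_length(unlist(empty$barcode), 0L)
})

test_that("tree-ensemble importance ranks the true regulator first", {
  n <- 500
  top_hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    tfs <- sprintf("TF%02d", 1:21)
    x <- matrix(rnorm(21 * n), 21, n, dimnames = list(tfs))
    y <- 2 * x["TF01", ] + rnorm(n, 0, 0.1)
    expr <- rbind(x, target = y)
    w <- importance_network(expr, tfs, "target", n_trees = 100, seed = s)
    if (which.max(w[, "target"]) == 1) top_hits <- top_hits + 1
    expect_equal(sum(w[, "target"]), 1, tolerance = 1e-9)
  }
  expect_gte(top_hits, n_seeds - 1)
})

test_that("importance handles degenerate targets and is deterministic", {
  set.seed(1)
  tfs <- sprintf("TF%d", 1:5)
  expr <- rbind(matrix(rnorm(5 * 40), 5, 40, dimnames = list(tfs)),
                flat = rep(1, 40))
  w <- importance_network(expr, tfs, "flat", n_trees = 50, seed = 3)
  expect_true(all(w == 0))
  expr2 <- rbind(expr[1:5, ], tgt = expr["TF2", ] + rnorm(40, 0, 0.2))
  w1 <- importance_network(expr2, tfs, "tgt", n_trees = 50, seed = 3)
  w2 <- importance_network(expr2, tfs, "tgt", n_trees = 50, seed = 3)
  expect_identical(w1, w2)
  # a target appearing among the TFs is dropped from its own predictors
  w3 <- importance_network(expr2, c(tfs, "tgt"), "tgt", n_trees = 20,
                           seed = 1)
  expect_identical(unname(w3["tgt", "tgt"]), 0)
  expect_error(importance_network(expr2[, 1:5], tfs, "tgt"), "10 samples")
})
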