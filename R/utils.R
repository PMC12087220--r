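# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible substream seed from a master seed and a stream name
#'
#' All stochastic components of the synthetic-data generator draw their seed
#' through this splitter, so adding a new component (a new named stream) never
#' perturbs the draws of existing ones.
#'
#' @param seed master integer seed.
#' @param name character stream name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  # small deterministic string hash (polynomial rolling, modular arithmetic
  # kept inside double precision integers)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((seed %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483647)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

assert_prob <- function(x, what) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

assert_count_matrix <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry gene (row) and sample (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("gene and sample identifiers must be unique", call. = FALSE)
  if (min(counts) < 0) stop("count matrix has negative entries", call. = FALSE)
  invisible(counts)
}

# upper-triangle vector of a symmetric labelled matrix
upper_tri_values <- function(m) m[upper.tri(m)]

new_pair_matrix <- function(values, measure, diagonal = c("similarity", "distance")) {
  diagonal <- match.arg(diagonal)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values, measure = measure, diagonal = diagonal,
            class = c("pair_matrix", class(values)))
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %s (%d x %d, %d missing pairs)\n",
              attr(x, "measure"), nrow(x), ncol(x),
              sum(is.na(x[upper.tri(x)]))))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))], ...)
  invisible(x)
}
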