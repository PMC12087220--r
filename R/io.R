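# Readers and writers for the plain-text interchange formats used throughout:
# MatrixMarket counts with sidecar name files, the annotation table dialect,
# JASPAR-style four-row motif records, dense TSV intensity grids, and labelled
# distance matrices. FASTA and Newick go through Biostrings and ape.

#' Write a counts matrix as MatrixMarket triplets plus name files
#'
#' @param counts integer matrix (genes x samples), dense or `Matrix` sparse.
#' @param dir output directory (created if missing).
#' @param prefix file prefix; writes `<prefix>.mtx`, `genes.txt`, and either
#'   `cells.txt` or `samples.txt` depending on `sample_file`.
#' @param sample_file name of the column-name sidecar file.
#' @return invisibly, the paths written.
#' @export
write_counts_mtx <- function(counts, dir, prefix = "counts",
                             sample_file = "cells.txt") {
  assert_count_matrix(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  mtx <- file.path(dir, paste0(prefix, ".mtx"))
  Matrix::writeMM(m, mtx)
  genes <- file.path(dir, "genes.txt")
  samples <- file.path(dir, sample_file)
  writeLines(rownames(counts), genes)
  writeLines(colnames(counts), samples)
  invisible(c(mtx = mtx, genes = genes, samples = samples))
}

#' Read a counts matrix written by [write_counts_mtx()]
#'
#' @param dir directory holding the files.
#' @inheritParams write_counts_mtx
#' @return a dense integer matrix with dimnames.
#' @export
read_counts_mtx <- function(dir, prefix = "counts", sample_file = "cells.txt") {
  m <- as.matrix(Matrix::readMM(file.path(dir, paste0(prefix, ".mtx"))))
  storage.mode(m) <- "double"
  rownames(m) <- readLines(file.path(dir, "genes.txt"))
  colnames(m) <- readLines(file.path(dir, sample_file))
  m
}

#' Read / write the gene annotation table
#'
#' Columns: gene_id, scaffold, start, end, strand (+/-), tss,
#' class (toxin/tf/other), family, group. Coordinates are 1-based inclusive.
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "scaffold", "start", "end", "strand", "tss",
                "class", "family", "group")
  missing <- setdiff(required, names(ann))
  if (length(missing))
    stop("annotation is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ann
}

#' @rdname read_annotation
#' @param annotation data.frame in the annotation dialect.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read position frequency matrices in four-row JASPAR text format
#'
#' Records look like `>MA0001.1 NAME` followed by four rows (A, C, G, T) of
#' counts, bracketed (`A [ 1 2 3 ]`) or bare.
#'
#' @param path motif text file.
#' @return a named list of `pfm` objects (fields `id`, `name`, `counts`:
#'   a 4 x L matrix with rownames A,C,G,T).
#' @export
read_pfms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif records found in ", path, call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  pfms <- lapply(seq_along(starts), function(i) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else parts[1]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4L)
      stop("motif record '", id, "' must have exactly 4 base rows, found ",
           length(body), call. = FALSE)
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]?\\s*\\[?", "", l)
      l <- gsub("\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    len <- unique(lengths(rows))
    if (length(len) != 1L)
      stop("motif record '", id, "' has rows of unequal length", call. = FALSE)
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(colSums(counts) <= 0))
      stop("motif record '", id, "' has a zero-sum column", call. = FALSE)
    structure(list(id = id, name = name, counts = counts), class = "pfm")
  })
  names(pfms) <- vapply(pfms, `[[`, "", "id")
  pfms
}

#' @rdname read_pfms
#' @param pfms list of `pfm` objects.
#' @export
write_pfms <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write / read one dense intensity grid as TSV
#'
#' @param grid numeric matrix (rows x cols).
#' @param path TSV path.
#' @export
write_grid_tsv <- function(grid, path) {
  write.table(grid, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
read_grid_tsv <- function(path) {
  unname(as.matrix(read.delim(path, header = FALSE)))
}

#' Write / read a labelled symmetric matrix as TSV
#'
#' @param m labelled matrix.
#' @param path TSV path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read an ion-image stack from a fixture directory
#'
#' Expects one `<toxin>.tsv` grid per toxin plus `mask.tsv`; the axis runs
#' along `axis_dim` with anterior at index 1.
#'
#' @param dir directory of grids.
#' @param axis_dim "col" or "row": the anterior-to-posterior dimension.
#' @return an `ion_image_stack`.
#' @export
read_ion_images <- function(dir, axis_dim = c("col", "row")) {
  axis_dim <- match.arg(axis_dim)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  mask_file <- files[basename(files) == "mask.tsv"]
  if (!length(mask_file)) stop("mask.tsv not found in ", dir, call. = FALSE)
  img_files <- files[basename(files) != "mask.tsv"]
  images <- lapply(img_files, read_grid_tsv)
  names(images) <- sub("\\.tsv$", "", basename(img_files))
  mask <- read_grid_tsv(mask_file) > 0
  ion_image_stack(images, mask, axis_dim = axis_dim)
}
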