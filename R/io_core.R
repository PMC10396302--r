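#' Construct a UMI count matrix container
#'
#' The central container of the package: a sparse cells x genes matrix of
#' non-negative integer UMI counts, with unique cell and gene identifiers and
#' a per-gene mitochondrial flag. All pipeline stages operate on this
#' orientation (cells in rows), regardless of the on-disk convention.
#'
#' @param counts cells x genes matrix (dense or sparse) of non-negative
#'   integers.
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param mito_flags logical vector flagging mitochondrial genes; defaults to
#'   all `FALSE`.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (a `dgCMatrix` with dimnames), `cell_ids`, `gene_ids`, `mito_flags`.
#' @export
count_matrix <- function(counts, cell_ids, gene_ids, mito_flags = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(mito_flags)) mito_flags <- rep(FALSE, length(gene_ids))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids))
    stop("counts is ", nrow(counts), " x ", ncol(counts), " but ",
         length(cell_ids), " cell ids and ", length(gene_ids),
         " gene ids were given")
  if (anyDuplicated(cell_ids)) stop("cell ids are not unique")
  if (anyDuplicated(gene_ids)) stop("gene ids are not unique")
  if (length(mito_flags) != length(gene_ids))
    stop("mito_flags length (", length(mito_flags),
         ") != number of genes (", length(gene_ids), ")")
  x <- counts@x
  if (any(x < 0)) stop("counts contain negative entries")
  if (any(x != round(x))) stop("counts contain non-integer entries")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 mito_flags = as.logical(mito_flags)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", length(x$cell_ids), "cells x", length(x$gene_ids),
      "genes;", sum(x$mito_flags), "mitochondrial genes;",
      length(x$counts@x), "nonzero entries\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Read a 10x-style MatrixMarket bundle into a CountMatrix
#'
#' Reads a MatrixMarket coordinate matrix together with one-entry-per-line
#' barcode and feature files. On disk, 10x matrices are genes x cells; in
#' memory everything is cells x genes, so the matrix is transposed to that
#' orientation (orientation is inferred from which axis matches the barcode
#' and feature counts; square matrices are assumed to follow the 10x
#' genes x cells convention).
#'
#' @param matrix_path path to the `.mtx` file (coordinate, integer).
#' @param barcodes_path path to the barcodes file (one cell id per line;
#'   first tab-separated field is used).
#' @param features_path path to the features file (one gene per line; first
#'   field is the gene id, an optional second field is the feature name used
#'   for mitochondrial matching).
#' @param mito_prefix case-insensitive feature-name prefix flagging
#'   mitochondrial genes (default `"mt-"`).
#' @return A [count_matrix()].
#' @export
read_mtx_bundle <- function(matrix_path, barcodes_path, features_path,
                            mito_prefix = "mt-") {
  m <- Matrix::readMM(matrix_path)
  barcodes <- read_id_column(barcodes_path)
  feat <- utils::read.delim(features_path, header = FALSE,
                            stringsAsFactors = FALSE)
  gene_ids <- as.character(feat[[1]])
  gene_names <- if (ncol(feat) >= 2) as.character(feat[[2]]) else gene_ids
  ng <- length(gene_ids); nc <- length(barcodes)
  if (nrow(m) == ng && ncol(m) == nc) {
    m <- Matrix::t(m)                      # 10x convention: genes x cells
  } else if (nrow(m) == nc && ncol(m) == ng) {
    # already cells x genes
  } else {
    stop("matrix is ", nrow(m), " x ", ncol(m), " but there are ", nc,
         " barcodes and ", ng, " features")
  }
  mito <- startsWith(tolower(gene_names), tolower(mito_prefix))
  count_matrix(m, barcodes, gene_ids, mito)
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a CountMatrix as a 10x-style MatrixMarket bundle
#'
#' Inverse of [read_mtx_bundle()]: writes `matrix.mtx` (genes x cells, the
#' 10x on-disk convention), `barcodes.tsv` and `features.tsv` (gene id and
#' feature name columns) into `dir`.
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_mtx_bundle <- function(cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  Matrix::writeMM(Matrix::t(cm$counts), paths[1])
  writeLines(cm$cell_ids, paths[2])
  writeLines(paste(cm$gene_ids, cm$gene_ids, sep = "\t"), paths[3])
  invisible(paths)
}

#' Write a rectangular table as UTF-8 TSV
#'
#' One header row, no quoting, no row names. String and integer columns
#' round-trip bit-exactly through [read_tsv_table()]; non-integer numeric
#' columns are written at 6 significant digits.
#'
#' @param table a data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  tab <- table
  for (j in seq_along(tab)) {
    if (is.double(tab[[j]])) tab[[j]] <- signif(tab[[j]], 6)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#'
#' @param path input path.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read amino-acid sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token after `>`; sequences
#' are upper-cased and trailing `*` stop characters are stripped. Duplicate
#' ids and residues outside the 20 standard amino acids (plus `X`) are hard
#' errors naming the offending record.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*+$", "", seqs)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad))
    stop("non-amino-acid characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write amino-acid sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a gene-age (phylostratum) table
#'
#' Expects columns `gene_id` and `phylostratum_rank` (positive integers,
#' rank 1 = oldest), with an optional `stratum_name`.
#'
#' @param path TSV path.
#' @return A data.frame with class `GeneAgeTable`.
#' @export
read_gene_ages <- function(path) {
  tab <- read_tsv_table(path)
  if (!all(c("gene_id", "phylostratum_rank") %in% names(tab)))
    stop("gene-age table must have columns gene_id and phylostratum_rank")
  gene_age_table(tab$gene_id, tab$phylostratum_rank,
                 if ("stratum_name" %in% names(tab)) tab$stratum_name)
}

#' Construct a gene-age table
#'
#' @param gene_id character gene ids (unique).
#' @param phylostratum_rank positive integer ranks, 1 = oldest.
#' @param stratum_name optional stratum labels.
#' @return data.frame with class `GeneAgeTable`.
#' @export
gene_age_table <- function(gene_id, phylostratum_rank, stratum_name = NULL) {
  rank <- as.numeric(phylostratum_rank)
  if (any(is.na(rank)) || any(rank < 1) || any(rank != round(rank)))
    stop("phylostratum ranks must be integers >= 1")
  if (anyDuplicated(gene_id)) stop("duplicate gene ids in gene-age table")
  out <- data.frame(gene_id = as.character(gene_id),
                    phylostratum_rank = as.integer(rank),
                    stringsAsFactors = FALSE)
  if (!is.null(stratum_name)) out$stratum_name <- as.character(stratum_name)
  class(out) <- c("GeneAgeTable", "data.frame")
  out
}

#' Read a cross-species ortholog/homolog map
#'
#' Expects columns `gene_a`, `gene_b` and optionally `weight` (in `(0, 1]`,
#' defaulting to 1 when the column is absent). The map may be many-to-many
#' in both directions; duplicate `(gene_a, gene_b)` pairs are an error.
#'
#' @param path TSV path.
#' @return data.frame with class `OrthologMap`.
#' @export
read_ortholog_map <- function(path) {
  tab <- read_tsv_table(path)
  if (!all(c("gene_a", "gene_b") %in% names(tab)))
    stop("ortholog map must have columns gene_a and gene_b")
  ortholog_map(tab$gene_a, tab$gene_b,
               if ("weight" %in% names(tab)) tab$weight else NULL)
}

#' Construct an ortholog map
#'
#' @param gene_a,gene_b character gene ids of the two species.
#' @param weight optional weights in `(0, 1]` (default 1).
#' @return data.frame with class `OrthologMap`.
#' @export
ortholog_map <- function(gene_a, gene_b, weight = NULL) {
  if (is.null(weight)) weight <- rep(1, length(gene_a))
  if (any(weight <= 0) || any(weight > 1))
    stop("ortholog weights must lie in (0, 1]")
  key <- paste(gene_a, gene_b, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (gene_a, gene_b) pairs")
  out <- data.frame(gene_a = as.character(gene_a),
                    gene_b = as.character(gene_b),
                    weight = as.numeric(weight), stringsAsFactors = FALSE)
  class(out) <- c("OrthologMap", "data.frame")
  out
}

#' Read per-cell cluster labels from TSV
#'
#' Expects columns `cell_id` and `cluster_id`.
#'
#' @param path TSV path.
#' @return Named character vector (names = cell ids).
#' @export
read_labels <- function(path) {
  tab <- read_tsv_table(path)
  if (!all(c("cell_id", "cluster_id") %in% names(tab)))
    stop("label table must have columns cell_id and cluster_id")
  stats::setNames(as.character(tab$cluster_id), as.character(tab$cell_id))
}

#' Write per-cell cluster labels to TSV
#'
#' @param labels named character vector (names = cell ids).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  write_tsv_table(data.frame(cell_id = names(labels),
                             cluster_id = unname(labels),
                             stringsAsFactors = FALSE), path)
}
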