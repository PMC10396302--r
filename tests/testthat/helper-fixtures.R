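# shared fixture builders; everything is generated in code at test time

# write a tiny MatrixMarket bundle (genes x cells on disk, 10x convention)
write_tiny_bundle <- function(dir, counts_genes_by_cells, barcodes, features) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(counts_genes_by_cells, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  writeLines(features, file.path(dir, "features.tsv"))
  dir
}

# two well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per = 60, d = 5, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(stats::rnorm(n_per * d), n_per, d)
    b <- matrix(stats::rnorm(n_per * d), n_per, d)
    b[, 1] <- b[, 1] + sep
    coords <- rbind(a, b)
    rownames(coords) <- sprintf("cell%03d", seq_len(2 * n_per))
    list(coords = coords,
         truth = rep(c("blob1", "blob2"), each = n_per))
  })
}

# split every true cluster into two labels (to exercise merging)
split_labels <- function(labels, seed = 42) {
  withr::with_seed(seed, {
    out <- labels
    for (t in unique(labels)) {
      cells <- names(labels)[labels == t]
      half <- sample(cells, length(cells) %/% 2)
      out[half] <- paste0(t, "a")
      out[setdiff(cells, half)] <- paste0(t, "b")
    }
    out
  })
}

# exact permutation null of the rank-sum statistic W (group A of size n1)
perm_null_W <- function(values, n1) {
  r <- rank(values)
  n <- length(values)
  combos <- utils::combn(n, n1)
  colSums(matrix(r[combos], nrow = n1))
}

# upper-tail hypergeometric by explicit combinatorial enumeration
hyper_tail_enum <- function(k, K, N, n) {
  j <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# brute-force mutual kNN: double loop, ties by cell id
brute_mutual_nn <- function(A, B, k) {
  ids_a <- rownames(A); ids_b <- rownames(B)
  D <- as.matrix(stats::dist(rbind(A, B)))[seq_len(nrow(A)),
                                           nrow(A) + seq_len(nrow(B))]
  res <- list()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      top_i <- order(D[i, ], ids_b)[seq_len(k)]
      top_j <- order(D[, j], ids_a)[seq_len(k)]
      if (j %in% top_i && i %in% top_j)
        res[[length(res) + 1L]] <- c(ids_a[i], ids_b[j])
    }
  }
  if (!length(res)) return(data.frame(cell_a = character(0),
                                      cell_b = character(0)))
  out <- as.data.frame(do.call(rbind, res), stringsAsFactors = FALSE)
  names(out) <- c("cell_a", "cell_b")
  out
}

sorted_pair_keys <- function(pairs) {
  sort(paste(pairs$cell_a, pairs$cell_b, sep = "|"))
}

# a complete single-species input set on disk for pipeline runs
write_pipeline_inputs <- function(dir, seed = 61) {
  spec <- sim_spec(seed = seed, n_cells = 120, n_genes = 500,
                   n_clusters = 3, markers_per_cluster = 25,
                   n_precursors = 4, n_decoys = 30)
  sim <- simulate_counts(spec)
  write_mtx_bundle(sim$counts, dir)
  write_labels(split_labels(sim$labels), file.path(dir, "labels.tsv"))
  ages <- simulate_gene_ages(spec, sim$counts$gene_ids, sim$marker_map)
  write_tsv_table(ages, file.path(dir, "ages.tsv"))
  pp <- simulate_precursors(spec)
  write_fasta(pp$seqs, file.path(dir, "proteome.fa"))
  write_tsv_table(pp$signal_calls, file.path(dir, "signal_calls.tsv"))
  list(spec = spec, sim = sim)
}

base_config <- function(dir, out) {
  list(out_dir = out,
       inputs = list(mtx = file.path(dir, "matrix.mtx"),
                     barcodes = file.path(dir, "barcodes.tsv"),
                     features = file.path(dir, "features.tsv"),
                     labels = file.path(dir, "labels.tsv"),
                     ages = file.path(dir, "ages.tsv"),
                     proteome = file.path(dir, "proteome.fa"),
                     signal_calls = file.path(dir, "signal_calls.tsv")),
       qc = list(min_genes_per_cell = 50))
}
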