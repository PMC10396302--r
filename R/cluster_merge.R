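#' Parameters controlling iterative cluster merging
#'
#' A cluster pair is merged when fewer than `de_gene_threshold` genes are
#' differentially expressed between them. A gene counts as differentially
#' expressed when its Bonferroni-adjusted two-sided Wilcoxon rank-sum
#' p-value falls below `p_threshold` and its absolute log2 fold change (on
#' mean log-normalized expression, with a 1e-9 pseudocount) reaches
#' `min_abs_log2fc`. Bonferroni is deliberately conservative: it biases the
#' DE count downward and therefore the procedure toward merging, so only
#' robustly distinct clusters survive.
#'
#' @param de_gene_threshold merge when DE count is strictly below this
#'   (default 20).
#' @param p_threshold adjusted-p cutoff per gene (default 0.01).
#' @param min_abs_log2fc minimum |log2 fold change| (default 0.25).
#' @return A list of class `MergeParams`.
#' @export
merge_params <- function(de_gene_threshold = 20, p_threshold = 0.01,
                         min_abs_log2fc = 0.25) {
  stopifnot(de_gene_threshold >= 1, p_threshold > 0, p_threshold < 1,
            min_abs_log2fc >= 0)
  structure(list(de_gene_threshold = de_gene_threshold,
                 p_threshold = p_threshold,
                 min_abs_log2fc = min_abs_log2fc),
            class = "MergeParams")
}

#' Per-cluster average expression profiles
#'
#' @param em cells x genes log-normalized expression matrix.
#' @param labels named character vector of cluster labels (names = cell
#'   ids covering the rows of `em`).
#' @return clusters x genes dense matrix of per-gene arithmetic means.
#' @export
cluster_centroids <- function(em, labels) {
  labels <- labels[rownames(em)]
  if (any(is.na(labels))) stop("labels missing for some cells")
  cl <- sort(unique(labels))
  out <- matrix(0, length(cl), ncol(em),
                dimnames = list(cl, colnames(em)))
  for (c in cl) {
    rows <- which(labels == c)
    if (!length(rows)) stop("empty cluster: ", c)
    out[c, ] <- Matrix::colMeans(em[rows, , drop = FALSE])
  }
  out
}

#' Rank cluster pairs by centroid correlation
#'
#' All unordered cluster pairs sorted by Pearson correlation of their
#' centroid expression profiles, highest first; ties broken
#' lexicographically by `(c1, c2)`. A centroid with zero variance gets
#' correlation 0 against every partner, with a warning.
#'
#' @param centroids clusters x genes matrix from [cluster_centroids()].
#' @return data.frame with columns `c1`, `c2`, `r`, sorted.
#' @export
rank_cluster_pairs <- function(centroids) {
  k <- nrow(centroids)
  if (k < 2) stop("need at least 2 clusters")
  sds <- apply(centroids, 1, stats::sd)
  if (any(sds == 0))
    warning("constant centroid(s): ",
            paste(rownames(centroids)[sds == 0], collapse = ", "),
            "; correlations set to 0")
  R <- suppressWarnings(stats::cor(t(centroids)))
  R[!is.finite(R)] <- 0
  idx <- which(upper.tri(R), arr.ind = TRUE)
  cl <- rownames(centroids)
  out <- data.frame(c1 = cl[idx[, 1]], c2 = cl[idx[, 2]],
                    r = R[idx], stringsAsFactors = FALSE)
  swap <- out$c1 > out$c2
  tmp <- out$c1[swap]; out$c1[swap] <- out$c2[swap]; out$c2[swap] <- tmp
  out[order(-out$r, out$c1, out$c2), , drop = FALSE]
}

#' Count differentially expressed genes between two cell groups
#'
#' Per gene, a two-sided Wilcoxon rank-sum test (normal approximation with
#' tie and continuity correction) between the two groups, Bonferroni
#' adjusted across genes; a gene is DE when the adjusted p-value is below
#' `p_threshold` and the absolute log2 ratio of group means (pseudocount
#' 1e-9) is at least `min_abs_log2fc`. Symmetric in the two groups.
#'
#' @param em cells x genes log-normalized expression matrix.
#' @param cells_a,cells_b cell ids of the two groups (each of size >= 3).
#' @param params a [merge_params()] object.
#' @return List with `n_de` (integer) and `table` (per-gene statistics).
#' @export
de_gene_count <- function(em, cells_a, cells_b, params = merge_params()) {
  if (length(cells_a) < 3 || length(cells_b) < 3)
    stop("both groups need at least 3 cells")
  Xa <- as.matrix(em[cells_a, , drop = FALSE])
  Xb <- as.matrix(em[cells_b, , drop = FALSE])
  st <- ranksum_stats(rbind(Xa, Xb), nrow(Xa))
  p_adj <- stats::p.adjust(st[, "p"], method = "bonferroni")
  eps <- 1e-9
  mean_a <- colMeans(Xa); mean_b <- colMeans(Xb)
  lfc <- log2((mean_a + eps) / (mean_b + eps))
  de <- p_adj < params$p_threshold & abs(lfc) >= params$min_abs_log2fc
  tab <- data.frame(gene_id = colnames(em), W = st[, "W"], p = st[, "p"],
                    p_adj = p_adj, mean_a = mean_a, mean_b = mean_b,
                    log2fc = lfc, de = de, stringsAsFactors = FALSE,
                    row.names = NULL)
  list(n_de = sum(de), table = tab)
}

#' Iteratively merge transcriptionally similar clusters
#'
#' Repeats until a fixed point: recompute centroids, rank all cluster pairs
#' by centroid correlation (highest first), walk the ranked list and test
#' each pair with [de_gene_count()]; the first pair whose DE count is
#' strictly below `de_gene_threshold` is merged (the kept cluster is the
#' lexicographically smaller id), the merge is logged and the pass
#' restarts. Pairs where either side has fewer than 3 cells are never
#' merged. Terminates after at most `initial clusters - 1` merges; on
#' termination no testable pair falls below the threshold.
#'
#' @param em cells x genes log-normalized expression matrix.
#' @param labels named character vector of initial (over-clustered) labels.
#' @param params a [merge_params()] object.
#' @return List with `labels` (final named label vector) and `merge_log`
#'   (data.frame: `cluster_kept`, `cluster_absorbed`, `de_count`,
#'   `correlation`, `pass_index`).
#' @export
merge_iterate <- function(em, labels, params = merge_params()) {
  labels <- labels[rownames(em)]
  if (any(is.na(labels))) stop("labels missing for some cells")
  log_rows <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    if (length(unique(labels)) < 2) break
    cents <- cluster_centroids(em, labels)
    pairs <- rank_cluster_pairs(cents)
    sizes <- table(labels)
    merged <- FALSE
    for (i in seq_len(nrow(pairs))) {
      c1 <- pairs$c1[i]; c2 <- pairs$c2[i]
      if (sizes[[c1]] < 3 || sizes[[c2]] < 3) next
      dc <- de_gene_count(em, names(labels)[labels == c1],
                          names(labels)[labels == c2], params)
      if (dc$n_de < params$de_gene_threshold) {
        keep <- min(c1, c2); absorb <- max(c1, c2)
        labels[labels == absorb] <- keep
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(cluster_kept = keep, cluster_absorbed = absorb,
                     de_count = dc$n_de, correlation = pairs$r[i],
                     pass_index = pass, stringsAsFactors = FALSE)
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  merge_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(cluster_kept = character(0), cluster_absorbed = character(0),
               de_count = integer(0), correlation = numeric(0),
               pass_index = integer(0), stringsAsFactors = FALSE)
  list(labels = labels, merge_log = merge_log)
}
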