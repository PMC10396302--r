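#' Transcriptome age index of one expression profile
#'
#' The TAI is the expression-weighted mean phylostratum rank of a
#' transcriptome: `TAI = sum(ps_g * e_g) / sum(e_g)` over genes `g` with a
#' known age and positive expression, where `ps_g` is the phylostratum rank
#' (1 = oldest, larger = younger) and `e_g` the log-transformed average
#' expression in the cluster. Larger TAI means an evolutionarily younger
#' expression profile. Genes without an age assignment are excluded (not
#' imputed) and counted.
#'
#' @param centroid_log_expr named numeric vector of log-normalized average
#'   expression per gene (names = gene ids).
#' @param ages a [gene_age_table()].
#' @return Numeric TAI, with attributes `n_genes_used` and
#'   `n_genes_missing_age`.
#' @export
cluster_tai <- function(centroid_log_expr, ages) {
  expressed <- centroid_log_expr[centroid_log_expr > 0]
  if (length(expressed) == 0) stop("no gene with positive expression")
  rank_map <- stats::setNames(ages$phylostratum_rank, ages$gene_id)
  ps <- rank_map[names(expressed)]
  used <- !is.na(ps)
  if (!any(used)) stop("no expressed gene has an age assignment")
  e <- expressed[used]
  tai <- sum(ps[used] * e) / sum(e)
  structure(tai, n_genes_used = sum(used), n_genes_missing_age = sum(!used))
}

#' Per-cluster TAI profile
#'
#' Applies [cluster_tai()] to each cluster's centroid of log-normalized
#' expression. Clusters in which no expressed gene has an age are reported
#' with `NA` (missing), never zero.
#'
#' @param em cells x genes log-normalized expression matrix.
#' @param labels named character vector of cluster labels.
#' @param ages a [gene_age_table()].
#' @return data.frame with columns `cluster_id`, `tai`, `n_genes_used`,
#'   `n_genes_missing_age`.
#' @export
tai_profile <- function(em, labels, ages) {
  cents <- cluster_centroids(em, labels)
  rows <- lapply(rownames(cents), function(c) {
    res <- tryCatch(cluster_tai(cents[c, ], ages), error = function(e) NULL)
    if (is.null(res))
      data.frame(cluster_id = c, tai = NA_real_, n_genes_used = 0L,
                 n_genes_missing_age = sum(cents[c, ] > 0),
                 stringsAsFactors = FALSE)
    else
      data.frame(cluster_id = c, tai = as.numeric(res),
                 n_genes_used = attr(res, "n_genes_used"),
                 n_genes_missing_age = attr(res, "n_genes_missing_age"),
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-vs-rest marker genes per cluster
#'
#' For each cluster, a two-sided Wilcoxon rank-sum test of each gene in the
#' cluster versus all other cells, Benjamini-Hochberg adjusted across genes
#' within the cluster. A gene is a marker when the adjusted p-value is below
#' `p_threshold`, the log2 fold change (in-cluster over out-of-cluster mean,
#' pseudocount 1e-9) is at least `min_log2fc`, and the in-cluster mean
#' exceeds the out-of-cluster mean.
#'
#' @param em cells x genes log-normalized expression matrix.
#' @param labels named character vector of cluster labels (>= 2 clusters).
#' @param p_threshold adjusted-p cutoff (default 0.05).
#' @param min_log2fc minimum log2 fold change (default 0.25).
#' @return data.frame (`MarkerTable`) with columns `cluster_id`, `gene_id`,
#'   `p`, `adjusted_p`, `log2fc`, `mean_in`, `mean_out`.
#' @export
find_markers <- function(em, labels, p_threshold = 0.05, min_log2fc = 0.25) {
  labels <- labels[rownames(em)]
  if (any(is.na(labels))) stop("labels missing for some cells")
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least 2 clusters to define markers")
  X <- as.matrix(em)
  eps <- 1e-9
  out <- lapply(cl, function(c) {
    in_rows <- which(labels == c)
    Z <- rbind(X[in_rows, , drop = FALSE], X[-in_rows, , drop = FALSE])
    st <- ranksum_stats(Z, length(in_rows))
    p_adj <- stats::p.adjust(st[, "p"], method = "BH")
    mean_in <- colMeans(X[in_rows, , drop = FALSE])
    mean_out <- colMeans(X[-in_rows, , drop = FALSE])
    lfc <- log2((mean_in + eps) / (mean_out + eps))
    is_marker <- p_adj < p_threshold & lfc >= min_log2fc & mean_in > mean_out
    data.frame(cluster_id = rep(c, sum(is_marker)),
               gene_id = colnames(X)[is_marker],
               p = st[is_marker, "p"], adjusted_p = p_adj[is_marker],
               log2fc = lfc[is_marker], mean_in = mean_in[is_marker],
               mean_out = mean_out[is_marker],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Hypergeometric phylostratum enrichment of cluster markers
#'
#' For cluster `c` and phylostratum `s`, with `N` background genes of which
#' `K` lie in `s`, and `n` markers of `c` of which `k` lie in `s`, the
#' over-representation p-value is the upper hypergeometric tail
#' `P(X >= k)`. Clusters without markers get p = 1 (flagged in the
#' `no_markers` column). No multiple-testing correction is applied to the
#' raw grid (the conventional way these heatmaps are drawn); a BH-adjusted
#' column is emitted alongside. P-values are floored at 1e-300 so
#' `-log10(p)` stays finite.
#'
#' @param markers a marker table from [find_markers()].
#' @param ages a [gene_age_table()].
#' @param background character vector of background gene ids (all expressed
#'   genes); markers must be a subset.
#' @return data.frame (`EnrichmentGrid`, long format) with columns
#'   `cluster_id`, `phylostratum`, `k`, `n`, `K`, `N`, `p_value`,
#'   `neg_log10_p`, `p_bh`, `no_markers`.
#' @export
phylostratum_enrichment <- function(markers, ages, background) {
  rank_map <- stats::setNames(ages$phylostratum_rank, ages$gene_id)
  background <- unique(background)
  background <- background[!is.na(rank_map[background])]
  if (!length(background)) stop("no background gene has an age assignment")
  if (!all(markers$gene_id %in% background))
    stop("marker genes must be a subset of the background")
  bg_rank <- rank_map[background]
  strata <- sort(unique(bg_rank))
  N <- length(background)
  clusters <- sort(unique(markers$cluster_id))
  rows <- list()
  for (c in clusters) {
    mg <- unique(markers$gene_id[markers$cluster_id == c])
    n <- length(mg)
    for (s in strata) {
      K <- sum(bg_rank == s)
      k <- sum(rank_map[mg] == s)
      p <- if (n == 0) 1 else
        stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      p <- max(p, 1e-300)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster_id = c, phylostratum = s, k = k, n = n, K = K,
                   N = N, p_value = p, neg_log10_p = -log10(p),
                   no_markers = n == 0, stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  grid$p_bh <- stats::p.adjust(grid$p_value, method = "BH")
  grid
}

#' Fold coverage of a cell capture over an organism's cell count
#'
#' For a larva with at most `cells_per_organism` cells, capturing `n_cells`
#' cells samples each larval cell `n_cells / cells_per_organism` times on
#' average; values well above 1 suggest even rare cell types were seen.
#'
#' @param n_cells cells captured in the dataset.
#' @param cells_per_organism upper bound on cells per organism.
#' @return Numeric fold coverage.
#' @export
capture_coverage_fold <- function(n_cells, cells_per_organism) {
  stopifnot(n_cells > 0, cells_per_organism > 0)
  n_cells / cells_per_organism
}
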