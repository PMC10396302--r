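#' Quality-control parameters for cell filtering
#'
#' Defaults follow common droplet scRNA-seq practice for small invertebrate
#' larvae: cells need at least 200 detected genes, at most 20% mitochondrial
#' counts (a more permissive 30% is typical for flatworm data), and a total
#' UMI bound of 5000. The side of the UMI bound is configurable because an
#' upper bound at 5000 is unusually low for deeply sequenced libraries;
#' `umi_bound_side = "upper"` discards cells strictly above the bound,
#' `"lower"` strictly below.
#'
#' @param min_genes_per_cell minimum detected genes per cell (default 200).
#' @param max_mito_fraction maximum mitochondrial count fraction
#'   (default 0.20).
#' @param umi_bound total-UMI bound (default 5000).
#' @param umi_bound_side `"upper"` (default) or `"lower"`.
#' @return A list of class `QCParams`.
#' @export
qc_params <- function(min_genes_per_cell = 200, max_mito_fraction = 0.20,
                      umi_bound = 5000, umi_bound_side = c("upper", "lower")) {
  umi_bound_side <- match.arg(umi_bound_side)
  stopifnot(min_genes_per_cell >= 0, max_mito_fraction >= 0,
            max_mito_fraction <= 1, umi_bound >= 0)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 umi_bound = umi_bound, umi_bound_side = umi_bound_side),
            class = "QCParams")
}

#' Filter low-quality cells and empty genes
#'
#' Removes cells with strictly fewer than `min_genes_per_cell` detected
#' genes, mitochondrial fraction strictly above `max_mito_fraction`, or
#' total UMI strictly beyond `umi_bound` on the configured side (a cell at
#' exactly the bound is kept). Genes left with zero counts are then dropped.
#'
#' @param cm a [count_matrix()].
#' @param qc a [qc_params()] object.
#' @return List with elements `counts` (the filtered [count_matrix()]) and
#'   `report` (per-criterion removal counts and dropped gene ids).
#' @export
filter_cells <- function(cm, qc = qc_params()) {
  X <- cm$counts
  detected <- Matrix::rowSums(X > 0)
  total <- Matrix::rowSums(X)
  mito_total <- if (any(cm$mito_flags))
    Matrix::rowSums(X[, cm$mito_flags, drop = FALSE]) else numeric(nrow(X))
  mito_frac <- ifelse(total > 0, mito_total / total, 0)
  low_genes <- detected < qc$min_genes_per_cell
  high_mito <- mito_frac > qc$max_mito_fraction
  bad_umi <- if (qc$umi_bound_side == "upper") total > qc$umi_bound
             else total < qc$umi_bound
  drop <- low_genes | high_mito | bad_umi
  if (all(drop))
    stop("all ", nrow(X), " cells removed by QC; review qc_params()")
  kept <- X[!drop, , drop = FALSE]
  empty_gene <- Matrix::colSums(kept) == 0
  report <- list(n_input_cells = nrow(X),
                 n_removed_low_genes = sum(low_genes),
                 n_removed_high_mito = sum(high_mito),
                 n_removed_umi_bound = sum(bad_umi),
                 n_removed_total = sum(drop),
                 n_kept_cells = sum(!drop),
                 dropped_genes = cm$gene_ids[empty_gene])
  out <- count_matrix(kept[, !empty_gene, drop = FALSE],
                      cm$cell_ids[!drop], cm$gene_ids[!empty_gene],
                      cm$mito_flags[!empty_gene])
  list(counts = out, report = report)
}

#' Library-size normalization with log1p transform
#'
#' Each cell's counts are divided by the cell's total count, multiplied by
#' `scale` (10,000 by default) and natural-log transformed with `log1p`:
#' `value = ln(1 + scale * count / total)`.
#'
#' @param cm a [count_matrix()].
#' @param scale scale factor (default 1e4).
#' @return A sparse cells x genes `dgCMatrix` of log-normalized expression
#'   with cell/gene dimnames.
#' @export
normalize_log1p <- function(cm, scale = 10000) {
  total <- Matrix::rowSums(cm$counts)
  if (any(total == 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(cm$cell_ids[total == 0], 5), collapse = ", "),
         "; run filter_cells() first")
  em <- Matrix::Diagonal(x = scale / total) %*% cm$counts
  em@x <- log1p(em@x)
  dimnames(em) <- dimnames(cm$counts)
  methods::as(em, "CsparseMatrix")
}

#' Select highly variable genes (variance-stabilizing flavor)
#'
#' Per gene, the mean and variance of the raw counts are computed; a loess
#' trend of log10 variance on log10 mean (span `loess_span`) gives each
#' gene a trend-expected standard deviation; counts are standardized by it,
#' values clipped at a ceiling of `sqrt(n_cells)`, and genes are ranked by
#' the variance of the clipped standardized counts. Ties are broken by gene
#' id so the selection is deterministic.
#'
#' @param cm a [count_matrix()].
#' @param n number of genes to select (default 2000).
#' @param loess_span span of the mean-variance trend fit (default 0.3).
#' @return Character vector of the selected gene ids (standardized-variance
#'   scores attached as the `"score"` attribute). If fewer than `n` genes
#'   have nonzero variance, all eligible genes are returned with a warning.
#' @export
select_variable_genes <- function(cm, n = 2000, loess_span = 0.3) {
  X <- cm$counts
  nc <- nrow(X)
  mu <- Matrix::colMeans(X)
  ex2 <- Matrix::colMeans(X ^ 2)
  v <- (ex2 - mu ^ 2) * nc / max(nc - 1, 1)
  eligible <- which(v > 0 & mu > 0)
  if (length(eligible) == 0) stop("no genes with nonzero variance")
  fit <- stats::loess(log10(v[eligible]) ~ log10(mu[eligible]),
                      span = loess_span, degree = 2)
  sd_exp <- sqrt(10 ^ stats::predict(fit))
  clip <- sqrt(nc)
  # standardized variance, computed sparse-aware per eligible gene
  Xe <- X[, eligible, drop = FALSE]
  nnz <- diff(Xe@p)
  gidx <- rep.int(seq_along(eligible), nnz)
  z <- pmin((Xe@x - mu[eligible][gidx]) / sd_exp[gidx], clip)
  z0 <- pmin(-mu[eligible] / sd_exp, clip)    # standardized value of a zero
  sum_z <- rowsum_vec(z, gidx, length(eligible)) + (nc - nnz) * z0
  sum_z2 <- rowsum_vec(z ^ 2, gidx, length(eligible)) + (nc - nnz) * z0 ^ 2
  std_var <- (sum_z2 - sum_z ^ 2 / nc) / max(nc - 1, 1)
  ids <- cm$gene_ids[eligible]
  ord <- order(-std_var, ids)
  if (length(eligible) < n) {
    warning("only ", length(eligible), " genes with nonzero variance; ",
            "returning all of them")
    n <- length(eligible)
  }
  sel <- ord[seq_len(n)]
  structure(ids[sel], score = unname(std_var[sel]))
}

rowsum_vec <- function(x, group, ngroups) {
  out <- numeric(ngroups)
  if (length(x)) {
    s <- rowsum(x, group)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' PCA embedding of log-normalized expression
#'
#' Restricts to the given genes, centers and unit-scales each gene (constant
#' genes contribute zeros), clips standardized values at `±clip`, and
#' projects onto the top `d` principal axes. The sign of each axis is fixed
#' by forcing its largest-magnitude gene loading to be positive, so the
#' embedding is fully deterministic.
#'
#' @param em cells x genes expression matrix ([normalize_log1p()] output).
#' @param genes gene ids to use (e.g. from [select_variable_genes()]).
#' @param d number of components (default 70).
#' @param clip clipping bound for standardized values (default 10).
#' @return cells x d coordinate matrix with cell ids as rownames.
#' @export
embed_pca <- function(em, genes, d = 70, clip = 10) {
  genes <- intersect(genes, colnames(em))
  X <- as.matrix(em[, genes, drop = FALSE])
  if (d > min(dim(X)))
    stop("d = ", d, " exceeds min(cells, genes) = ", min(dim(X)))
  X <- scale(X)
  X[is.na(X)] <- 0                      # constant genes
  X[X > clip] <- clip
  X[X < -clip] <- -clip
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = d)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(em)
  scores
}

#' Initial over-clustering on a shared-nearest-neighbor graph
#'
#' Builds a k-nearest-neighbor graph (Euclidean distances in the embedding,
#' ties broken by cell id), converts it to a shared-nearest-neighbor graph
#' with Jaccard edge weights, prunes weak edges, and partitions it with
#' seeded multilevel (Louvain) modularity optimization at the given
#' resolution. High resolutions deliberately over-cluster; the downstream
#' merge step corrects this. Cells isolated after pruning become singleton
#' clusters with a warning.
#'
#' @param emb cells x d embedding ([embed_pca()] output).
#' @param resolution modularity resolution (default 10).
#' @param k_neighbors neighbors per cell (default 20).
#' @param seed RNG seed for the community detection (default 0).
#' @param prune minimum Jaccard weight to keep an edge (default 1/15).
#' @return Named character vector of cluster labels (names = cell ids).
#' @export
initial_clusters <- function(emb, resolution = 10, k_neighbors = 20,
                             seed = 0, prune = 1 / 15) {
  n <- nrow(emb)
  if (n < k_neighbors + 1)
    stop("need at least k_neighbors + 1 = ", k_neighbors + 1, " cells")
  ids <- rownames(emb)
  if (is.null(ids)) ids <- paste0("cell", seq_len(n))
  D <- as.matrix(stats::dist(emb))
  knn <- matrix(0L, n, k_neighbors)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], ids)
    ord <- ord[ord != i]
    knn[i, ] <- ord[seq_len(k_neighbors)]
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                            j = as.vector(t(knn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)       # shared-neighbor counts
  S <- methods::as(Matrix::triu(shared, k = 1), "TsparseMatrix")
  w <- S@x / (2 * k_neighbors - S@x)    # Jaccard of two k-sets
  keep <- w >= prune
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(S@i[keep] + 1L, S@j[keep] + 1L),
                           weight = w[keep])
  isolated <- igraph::degree(g) == 0
  if (any(isolated))
    warning(sum(isolated), " isolated cell(s) form singleton clusters")
  memb <- withr::with_seed(seed, {
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    igraph::membership(cl)
  })
  stats::setNames(paste0("c", as.integer(memb)), ids)
}
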