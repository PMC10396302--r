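#' Collapse two species' expression matrices into a shared ortholog space
#'
#' Builds the bipartite ortholog graph from the map, takes its connected
#' components as shared features, and represents each feature in each
#' species as the weight-normalized average of its member genes' expression
#' (a gene's weight is the total weight of its ortholog edges, so a 1:1
#' pair with weight 1 passes each gene through unchanged). Components with
#' members in only one species are dropped and counted; map records that
#' reference genes absent from either matrix are skipped with a warning.
#'
#' @param em_a,em_b cells x genes log-normalized expression matrices of the
#'   two species.
#' @param omap an [ortholog_map()].
#' @return List with `a` and `b` (cells x features matrices over the same
#'   feature axis), `n_features`, `n_dropped_one_sided`,
#'   `n_skipped_records`.
#' @export
collapse_to_ortholog_space <- function(em_a, em_b, omap) {
  present <- omap$gene_a %in% colnames(em_a) & omap$gene_b %in% colnames(em_b)
  n_skip <- sum(!present)
  if (n_skip > 0)
    warning(n_skip, " ortholog record(s) reference absent genes; skipped")
  om <- omap[present, , drop = FALSE]
  if (nrow(om) == 0) stop("no ortholog record matches both matrices")
  va <- paste0("A\r", om$gene_a)
  vb <- paste0("B\r", om$gene_b)
  g <- igraph::graph_from_data_frame(data.frame(va, vb), directed = FALSE)
  comp <- igraph::components(g)$membership
  node <- names(comp)
  species <- substr(node, 1, 1)
  gene <- substring(node, 3)
  # total incident edge weight per gene = its weight in the feature average
  wa <- rowsum(om$weight, va); wb <- rowsum(om$weight, vb)
  w <- numeric(length(node))
  w[species == "A"] <- wa[match(node[species == "A"], rownames(wa)), 1]
  w[species == "B"] <- wb[match(node[species == "B"], rownames(wb)), 1]
  two_sided <- intersect(unique(comp[species == "A"]),
                         unique(comp[species == "B"]))
  n_dropped <- comp_count <- max(comp)
  n_dropped <- length(unique(comp)) - length(two_sided)
  feat_id <- stats::setNames(seq_along(two_sided), two_sided)
  keep <- comp %in% two_sided
  f <- feat_id[as.character(comp[keep])]
  sp <- species[keep]; gn <- gene[keep]; wk <- w[keep]
  make_map <- function(em, which_sp) {
    sel <- sp == which_sp
    M <- Matrix::sparseMatrix(i = match(gn[sel], colnames(em)),
                              j = f[sel], x = wk[sel],
                              dims = c(ncol(em), length(two_sided)))
    tot <- Matrix::colSums(M)
    M %*% Matrix::Diagonal(x = 1 / tot)
  }
  fa <- em_a %*% make_map(em_a, "A")
  fb <- em_b %*% make_map(em_b, "B")
  fa <- as.matrix(fa); fb <- as.matrix(fb)
  fnames <- paste0("feat", seq_along(two_sided))
  colnames(fa) <- colnames(fb) <- fnames
  rownames(fa) <- rownames(em_a); rownames(fb) <- rownames(em_b)
  list(a = fa, b = fb, n_features = length(two_sided),
       n_dropped_one_sided = n_dropped, n_skipped_records = n_skip)
}

#' Joint PCA embedding of two species over a shared feature axis
#'
#' Each species' features are standardized within species (constant
#' features contribute zeros), the cell x feature blocks are concatenated,
#' and the combined matrix is projected onto `d` sign-fixed principal axes
#' (largest-magnitude loading positive, as in [embed_pca()]).
#'
#' @param mat_a,mat_b cells x features matrices over the same feature axis
#'   (from [collapse_to_ortholog_space()]).
#' @param d number of components (default 30).
#' @return List with `a` and `b`: cells x d coordinate matrices.
#' @export
joint_embedding <- function(mat_a, mat_b, d = 30) {
  if (ncol(mat_a) != ncol(mat_b)) stop("feature axes differ")
  std <- function(m) {
    z <- scale(m)
    z[is.na(z)] <- 0
    z
  }
  Z <- rbind(std(mat_a), std(mat_b))
  if (d > min(dim(Z))) stop("d = ", d, " too large for ", nrow(Z), " x ",
                            ncol(Z), " joint matrix")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE, rank. = d)
  rot <- pc$rotation; scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  na <- nrow(mat_a)
  a <- scores[seq_len(na), , drop = FALSE]
  b <- scores[na + seq_len(nrow(mat_b)), , drop = FALSE]
  rownames(a) <- rownames(mat_a); rownames(b) <- rownames(mat_b)
  list(a = a, b = b)
}

#' Mutual nearest cross-species neighbor pairs
#'
#' A pair `(x, y)` is reported iff `y` is among the `k` nearest cells of
#' the other species to `x` and vice versa (Euclidean distance in the joint
#' embedding). Distance ties are broken by cell id, so the output is
#' deterministic.
#'
#' @param emb list with `a` and `b` coordinate matrices
#'   ([joint_embedding()] output).
#' @param k neighbors per cell (default 20); each species must have more
#'   than `k` cells.
#' @return data.frame with columns `cell_a`, `cell_b`.
#' @export
mutual_nn <- function(emb, k = 20) {
  A <- emb$a; B <- emb$b
  if (nrow(A) <= k || nrow(B) <= k)
    stop("each species needs more than k = ", k, " cells")
  ids_a <- rownames(A); ids_b <- rownames(B)
  D <- cross_dist(A, B)
  topk <- function(d, ids) order(d, ids)[seq_len(k)]
  # each a-cell's knn in B, and vice versa (explicit shape: k = 1 safe)
  nn_ab <- matrix(vapply(seq_len(nrow(A)), function(i) topk(D[i, ], ids_b),
                         integer(k)), ncol = k, byrow = TRUE)
  nn_ba <- matrix(vapply(seq_len(nrow(B)), function(j) topk(D[, j], ids_a),
                         integer(k)), ncol = k, byrow = TRUE)
  in_ba <- matrix(FALSE, nrow(B), nrow(A))
  for (j in seq_len(nrow(B))) in_ba[j, nn_ba[j, ]] <- TRUE
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (i in seq_len(nrow(A))) {
    js <- nn_ab[i, ]
    mut <- js[in_ba[js, i]]
    pairs_a <- c(pairs_a, rep.int(i, length(mut)))
    pairs_b <- c(pairs_b, mut)
  }
  data.frame(cell_a = ids_a[pairs_a], cell_b = ids_b[pairs_b],
             stringsAsFactors = FALSE)
}

cross_dist <- function(A, B) {
  sq <- outer(rowSums(A ^ 2), rowSums(B ^ 2), "+") - 2 * tcrossprod(A, B)
  sq[sq < 0] <- 0
  sqrt(sq)
}

#' Cross-species cluster alignment scores
#'
#' For clusters `c` (species A) and `d` (species B), the directional score
#' `s_c` is the mean over cells `x` in `c` of the number of x's mutual
#' cross-species partners lying in `d`, divided by `k` (the maximum
#' possible number of neighbors); `s_d` is defined symmetrically and the
#' reported score is `(s_c + s_d) / 2`, which lies in `[0, 1]`. The full
#' matrix is returned together with a pruned view in which scores below
#' `prune_below` are zeroed.
#'
#' @param pairs mutual-pair data.frame from [mutual_nn()].
#' @param labels_a,labels_b named character label vectors covering all
#'   embedded cells of each species.
#' @param k the `k` used in [mutual_nn()].
#' @param prune_below threshold for the pruned view (default 0.1).
#' @return List with `full` and `pruned` (clusters_a x clusters_b
#'   matrices) and `directional` (long data.frame with `s_ab`, `s_ba`).
#' @export
alignment_scores <- function(pairs, labels_a, labels_b, k,
                             prune_below = 0.1) {
  cla <- sort(unique(labels_a)); clb <- sort(unique(labels_b))
  full <- matrix(0, length(cla), length(clb), dimnames = list(cla, clb))
  s_ab <- full; s_ba <- full
  pc_a <- labels_a[pairs$cell_a]
  pc_b <- labels_b[pairs$cell_b]
  for (ca in cla) {
    n_ca <- sum(labels_a == ca)
    for (cb in clb) {
      n_cb <- sum(labels_b == cb)
      n_pairs <- sum(pc_a == ca & pc_b == cb)
      sab <- n_pairs / (n_ca * k)   # mean over cells in ca of partners-in-cb / k
      sba <- n_pairs / (n_cb * k)
      s_ab[ca, cb] <- sab; s_ba[ca, cb] <- sba
      full[ca, cb] <- (sab + sba) / 2
    }
  }
  pruned <- full
  pruned[pruned < prune_below] <- 0
  directional <- data.frame(cluster_a = rep(cla, times = length(clb)),
                            cluster_b = rep(clb, each = length(cla)),
                            s_ab = as.vector(s_ab), s_ba = as.vector(s_ba),
                            score = as.vector(full),
                            stringsAsFactors = FALSE)
  list(full = full, pruned = pruned, directional = directional)
}

#' Shared markers of an aligned cross-species cluster pair
#'
#' All ortholog records whose `gene_a` is a marker of `cluster_a` and whose
#' `gene_b` is a marker of `cluster_b`. Because the map may be many-to-many,
#' the per-species counts of distinct genes can differ.
#'
#' @param markers_a,markers_b marker tables ([find_markers()] output) of
#'   the two species.
#' @param omap an [ortholog_map()].
#' @param cluster_a,cluster_b the cluster ids to compare.
#' @return List with `records` (subset of the map), `n_genes_a`,
#'   `n_genes_b`.
#' @export
shared_markers <- function(markers_a, markers_b, omap, cluster_a, cluster_b) {
  ga <- unique(markers_a$gene_id[markers_a$cluster_id == cluster_a])
  gb <- unique(markers_b$gene_id[markers_b$cluster_id == cluster_b])
  rec <- omap[omap$gene_a %in% ga & omap$gene_b %in% gb, , drop = FALSE]
  list(records = rec, n_genes_a = length(unique(rec$gene_a)),
       n_genes_b = length(unique(rec$gene_b)))
}
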