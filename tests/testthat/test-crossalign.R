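toy_em <- function(ids, genes, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rexp(length(ids) * length(genes)),
                length(ids), length(genes),
                dimnames = list(ids, genes))
  })
  m
}

test_that("collapse_to_ortholog_space handles 1:1, many-to-one and absent genes", {
  em_a <- toy_em(c("a1", "a2"), c("g1", "g2", "g3"), 1)
  em_b <- toy_em(c("b1", "b2", "b3"), c("h1", "h2"), 2)
  # 1:1 with weight 1: features are a column subset/reorder
  omap <- ortholog_map(c("g2", "g1"), c("h1", "h2"))
  res <- collapse_to_ortholog_space(em_a, em_b, omap)
  expect_equal(res$n_features, 2L)
  expect_equal(sort(as.vector(res$a)), sort(as.vector(em_a[, c("g1", "g2")])))
  expect_equal(sort(as.vector(res$b)), sort(as.vector(em_b)))

  # g1, g2 -> h1 (weights 1): A feature = mean(g1, g2), B feature = h1
  omap2 <- ortholog_map(c("g1", "g2"), c("h1", "h1"))
  res2 <- collapse_to_ortholog_space(em_a, em_b, omap2)
  expect_equal(res2$n_features, 1L)
  expect_equal(as.vector(res2$a), unname(rowMeans(em_a[, c("g1", "g2")])))
  expect_equal(as.vector(res2$b), as.vector(em_b[, "h1"]))

  # a record naming an absent gene is skipped with a warning and counted
  omap3 <- ortholog_map(c("g1", "gX"), c("h1", "h2"))
  expect_warning(res3 <- collapse_to_ortholog_space(em_a, em_b, omap3),
                 "absent")
  expect_equal(res3$n_skipped_records, 1L)
  expect_error(suppressWarnings(collapse_to_ortholog_space(
    em_a, em_b, ortholog_map("gX", "h1"))), "no ortholog record")
})

test_that("joint_embedding puts duplicated datasets on identical coordinates", {
  em <- toy_em(sprintf("a%02d", 1:40), sprintf("g%02d", 1:15), 3)
  em_b <- em; rownames(em_b) <- sprintf("b%02d", 1:40)
  emb <- joint_embedding(em, em_b, d = 5)
  expect_equal(unname(emb$a), unname(emb$b), tolerance = 1e-9)
  # permuting cells permutes rows correspondingly
  perm <- sample(40)
  emb_p <- joint_embedding(em[perm, ], em_b, d = 5)
  expect_equal(emb_p$a, emb$a[perm, ], tolerance = 1e-9)
  expect_error(joint_embedding(em, em_b[, 1:10], d = 5), "differ")
  expect_error(joint_embedding(em, em_b, d = 100), "too large")
})

test_that("mutual_nn finds twin pairs at k = 1 and matches the brute-force scan", {
  em <- toy_em(sprintf("a%02d", 1:25), sprintf("g%02d", 1:8), 4)
  twin <- list(a = em, b = `rownames<-`(em, sprintf("b%02d", 1:25)))
  pairs <- mutual_nn(twin, k = 1)
  expect_equal(nrow(pairs), 25L)
  expect_equal(pairs$cell_b[order(pairs$cell_a)], sprintf("b%02d", 1:25))

  withr::with_seed(6, {
    A <- matrix(stats::rnorm(60 * 4), 60, 4,
                dimnames = list(sprintf("a%02d", 1:60), NULL))
    B <- matrix(stats::rnorm(50 * 4), 50, 4,
                dimnames = list(sprintf("b%02d", 1:50), NULL))
  })
  for (k in c(3, 7)) {
    got <- mutual_nn(list(a = A, b = B), k = k)
    want <- brute_mutual_nn(A, B, k)
    expect_identical(sorted_pair_keys(got), sorted_pair_keys(want))
  }
  # mutuality and monotonicity in k
  n_k <- vapply(c(2, 5, 10, 20), function(k)
    nrow(mutual_nn(list(a = A, b = B), k = k)), numeric(1))
  expect_true(all(diff(n_k) >= 0))
  expect_error(mutual_nn(list(a = A, b = B), k = 60), "more than k")
})

test_that("self-alignment through an identity map is the identity matrix", {
  sim <- simulate_counts(sim_spec(seed = 41, n_cells = 90, n_genes = 300,
                                  n_clusters = 3, markers_per_cluster = 20,
                                  mito_high_frac = 0))
  em <- normalize_log1p(sim$counts)
  em_b <- em; rownames(em_b) <- paste0("twin_", rownames(em))
  omap <- ortholog_map(colnames(em), colnames(em_b))
  coll <- collapse_to_ortholog_space(em, em_b, omap)
  emb <- joint_embedding(coll$a, coll$b, d = 20)
  pairs <- mutual_nn(emb, k = 1)
  labels_b <- stats::setNames(sim$labels, paste0("twin_", names(sim$labels)))
  sc <- alignment_scores(pairs, sim$labels, labels_b, k = 1)
  expect_true(all(diag(sc$full) == 1))
  expect_true(all(sc$full[upper.tri(sc$full)] == 0))
  expect_true(all(sc$full[lower.tri(sc$full)] == 0))
  # row-wise argmax of a self-comparison is the diagonal
  expect_equal(unname(apply(sc$full, 1, which.max)), seq_len(nrow(sc$full)))
})

test_that("alignment scores stay in [0,1] and are symmetric under species swap", {
  spec <- sim_spec(seed = 44)
  pair <- simulate_species_pair(spec)
  em_a <- normalize_log1p(pair$a); em_b <- normalize_log1p(pair$b)
  coll <- collapse_to_ortholog_space(em_a, em_b, pair$omap)
  emb <- joint_embedding(coll$a, coll$b, d = 30)
  pairs <- mutual_nn(emb, k = 20)
  sc <- alignment_scores(pairs, pair$labels_a, pair$labels_b, k = 20)
  expect_true(all(sc$full >= 0 & sc$full <= 1))
  swapped <- data.frame(cell_a = pairs$cell_b, cell_b = pairs$cell_a,
                        stringsAsFactors = FALSE)
  sc_sw <- alignment_scores(swapped, pair$labels_b, pair$labels_a, k = 20)
  expect_equal(sc_sw$full, t(sc$full))
  # pruned view zeroes sub-threshold entries but the full table keeps them
  expect_true(all(sc$pruned[sc$full < 0.1] == 0))
  expect_true(any(sc$full > 0))
})

test_that("shared_markers reproduces the unequal-count many-to-one phenomenon", {
  markers_a <- data.frame(cluster_id = "cilA", gene_id = c("g1", "g2"),
                          stringsAsFactors = FALSE)
  markers_b <- data.frame(cluster_id = "cilB", gene_id = "h",
                          stringsAsFactors = FALSE)
  omap <- ortholog_map(c("g1", "g2", "g3"), c("h", "h", "h2"))
  rep <- shared_markers(markers_a, markers_b, omap, "cilA", "cilB")
  expect_equal(rep$n_genes_a, 2L)
  expect_equal(rep$n_genes_b, 1L)
  # the report is a subset of the map
  expect_true(all(paste(rep$records$gene_a, rep$records$gene_b) %in%
                    paste(omap$gene_a, omap$gene_b)))
  # disjoint marker sets give an empty report
  none <- shared_markers(markers_a, data.frame(cluster_id = "cilB",
                                               gene_id = "h2"),
                         omap, "cilA", "cilB")
  expect_equal(nrow(none$records), 0L)
})
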