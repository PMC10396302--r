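test_that("cluster_centroids equals a brute-force per-gene mean", {
  withr::with_seed(21, {
    em <- matrix(stats::rexp(20 * 10), 20, 10,
                 dimnames = list(sprintf("c%02d", 1:20),
                                 sprintf("g%02d", 1:10)))
    labels <- stats::setNames(sample(c("x", "y", "z"), 20, replace = TRUE),
                              rownames(em))
  })
  cents <- cluster_centroids(em, labels)
  for (cl in c("x", "y", "z")) {
    manual <- apply(em[names(labels)[labels == cl], , drop = FALSE], 2, mean)
    expect_equal(cents[cl, ], manual)
  }
  # a singleton cluster's centroid is that cell's row
  labels1 <- labels; labels1[1] <- "solo"
  cents1 <- cluster_centroids(em, labels1)
  expect_equal(cents1["solo", ], em[1, ])
})

test_that("rank_cluster_pairs sorts by correlation with deterministic ties", {
  cents <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2,  # r = 1 with a
                 c = c(4, 3, 2, 1), d = c(1, 3, 2, 5))
  pr <- rank_cluster_pairs(cents)
  expect_equal(c(pr$c1[1], pr$c2[1]), c("a", "b"))    # identical profiles first
  expect_equal(pr$r[1], 1.0)
  expect_equal(pr$r[nrow(pr)], min(pr$r))
  # order agrees with a brute-force correlation sort
  brute <- as.vector(combn(rownames(cents), 2, function(p)
    stats::cor(cents[p[1], ], cents[p[2], ])))
  expect_equal(sort(pr$r, decreasing = TRUE), sort(brute, decreasing = TRUE))
  # centroid and its negation rank last
  expect_equal(pr[pr$c1 == "a" & pr$c2 == "c", "r"], -1.0)
  # constant centroid: correlation defined as 0 with a warning
  expect_warning(pr0 <- rank_cluster_pairs(rbind(a = c(1, 1, 1),
                                                 b = c(1, 2, 3))),
                 "constant")
  expect_equal(pr0$r, 0)
})

test_that("the rank-sum kernel agrees with wilcox.test and permutation nulls", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
      # ties are likely: integer-valued data
      x <- sample(0:4, n1 + n2, replace = TRUE)
      st <- larvatlas:::ranksum_stats(matrix(as.numeric(x)), n1)
      wt <- suppressWarnings(stats::wilcox.test(x[1:n1], x[-(1:n1)],
                                                exact = FALSE,
                                                correct = TRUE))
      expect_equal(unname(st[1, "p"]), wt$p.value, tolerance = 1e-12)
      expect_equal(unname(st[1, "W"]) - n1 * (n1 + 1) / 2,
                   unname(wt$statistic))
      # observed statistic matches brute-force ranks, and the
      # tie-corrected moments equal the exact permutation null's
      null_W <- perm_null_W(x, n1)
      expect_equal(unname(st[1, "W"]), sum(rank(x)[1:n1]))
      U <- unname(st[1, "W"]) - n1 * (n1 + 1) / 2
      expect_equal(mean(null_W) - n1 * (n1 + 1) / 2, n1 * n2 / 2)
      if (st[1, "z"] != 0) {
        sd_used <- unname((U - n1 * n2 / 2) / st[1, "z"])
        expect_equal(sd_used^2, mean((null_W - mean(null_W))^2),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("de_gene_count finds planted effects, nothing under the null, and is symmetric", {
  ng <- 500
  withr::with_seed(8, {
    em <- matrix(stats::rexp(40 * ng), 40, ng,
                 dimnames = list(sprintf("c%02d", 1:40),
                                 sprintf("g%03d", 1:ng)))
  })
  a <- rownames(em)[1:20]; b <- rownames(em)[21:40]
  # same distribution everywhere: no DE at Bonferroni 0.01
  expect_equal(de_gene_count(em, a, b)$n_de, 0L)

  # 30 genes with disjoint support (5 vs 0)
  em2 <- em
  em2[a, 1:30] <- 5; em2[b, 1:30] <- 0
  res <- de_gene_count(em2, a, b)
  expect_equal(res$n_de, 30L)
  expect_setequal(res$table$gene_id[res$table$de], sprintf("g%03d", 1:30))
  # symmetry
  expect_equal(de_gene_count(em2, b, a)$n_de, res$n_de)

  # identical constant groups: nothing
  em3 <- matrix(1, 10, 50, dimnames = list(sprintf("c%02d", 1:10),
                                           sprintf("g%03d", 1:50)))
  expect_equal(de_gene_count(em3, rownames(em3)[1:5],
                             rownames(em3)[6:10])$n_de, 0L)
  expect_error(de_gene_count(em, a[1:2], b), "3 cells")
})

test_that("merge_iterate is a fixed point on well-separated clusters", {
  sim <- simulate_counts(sim_spec(seed = 14, n_cells = 120, n_genes = 800,
                                  n_clusters = 3, markers_per_cluster = 30,
                                  mito_high_frac = 0))
  em <- normalize_log1p(sim$counts)
  res <- merge_iterate(em, sim$labels)
  expect_identical(sort(unique(res$labels)), sort(unique(sim$labels)))
  expect_equal(nrow(res$merge_log), 0L)
})

test_that("merge_iterate heals a planted split and leaves no mergeable pair", {
  spec <- sim_spec(seed = 15, n_cells = 180, n_genes = 1000,
                   n_clusters = 3, markers_per_cluster = 30,
                   mito_high_frac = 0)
  sim <- simulate_counts(spec)
  em <- normalize_log1p(sim$counts)
  split <- split_labels(sim$labels)
  expect_equal(length(unique(split)), 6L)
  res <- merge_iterate(em, split)
  expect_equal(length(unique(res$labels)), 3L)
  expect_equal(mclust::adjustedRandIndex(res$labels[names(sim$labels)],
                                         sim$labels), 1.0)
  # merge log is consistent: every entry below threshold, kept id smaller
  expect_true(all(res$merge_log$de_count < 20))
  expect_true(all(res$merge_log$cluster_kept < res$merge_log$cluster_absorbed))
  # audit: on termination no remaining testable pair is below threshold
  final <- res$labels
  cls <- unique(final)
  for (i in seq_along(cls)) for (j in seq_len(i - 1)) {
    ca <- names(final)[final == cls[i]]; cb <- names(final)[final == cls[j]]
    expect_gte(de_gene_count(em, ca, cb)$n_de, 20)
  }
  # cluster count never increases along the log
  expect_lte(nrow(res$merge_log), length(unique(split)) - 1)
})

test_that("cluster-blind data collapse to a single cluster", {
  spec <- sim_spec(seed = 16, n_cells = 90, n_genes = 500, n_clusters = 3,
                   marker_log2fc = 0, mito_high_frac = 0)
  sim <- simulate_counts(spec)
  em <- normalize_log1p(sim$counts)
  res <- merge_iterate(em, sim$labels)
  expect_equal(length(unique(res$labels)), 1L)
})
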