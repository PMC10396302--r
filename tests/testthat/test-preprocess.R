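make_qc_fixture <- function() {
  # 4 genes (one mito) x hand-built cells exercising each QC rule
  genes <- c("g1", "g2", "g3", "mt-1")
  mk <- function(...) c(...)
  counts <- rbind(
    ok       = mk(10, 10, 10, 1),
    low_gene = mk(31, 0, 0, 0),        # 1 detected gene
    hi_mito  = mk(3, 3, 2, 8),         # mito fraction 0.5
    at_bound = mk(2000, 2000, 999, 1)  # total exactly 5000
  )
  count_matrix(counts, rownames(counts), genes,
               mito_flags = genes == "mt-1")
}

test_that("filter_cells applies strict boundary semantics per criterion", {
  cm <- make_qc_fixture()
  qc <- qc_params(min_genes_per_cell = 2, max_mito_fraction = 0.20,
                  umi_bound = 5000)
  res <- filter_cells(cm, qc)
  expect_setequal(res$counts$cell_ids, c("ok", "at_bound"))
  expect_equal(res$report$n_removed_low_genes, 1L)
  expect_equal(res$report$n_removed_high_mito, 1L)
  expect_equal(res$report$n_removed_umi_bound, 0L)  # 5000 is kept (strict >)

  # a cell one UMI over the bound goes
  cm2 <- count_matrix(matrix(c(2501, 2500), 1, 2), "c1", c("g1", "g2"))
  expect_error(filter_cells(cm2, qc_params(min_genes_per_cell = 0,
                                           umi_bound = 5000)),
               "all .* removed")
  # lower-bound side flips the comparison
  res3 <- filter_cells(cm2, qc_params(min_genes_per_cell = 0,
                                      umi_bound = 5000,
                                      umi_bound_side = "lower"))
  expect_equal(res3$counts$cell_ids, "c1")
})

test_that("a cell with 199 detected genes is removed at default QC", {
  n <- 400
  counts <- rbind(cell199 = c(rep(1L, 199), rep(0L, n - 199)),
                  cell200 = c(rep(1L, 200), rep(0L, n - 200)),
                  big = rep(3L, n))
  cm <- count_matrix(counts, rownames(counts), sprintf("g%03d", 1:n))
  res <- filter_cells(cm, qc_params())
  expect_false("cell199" %in% res$counts$cell_ids)
  expect_true("cell200" %in% res$counts$cell_ids)
})

test_that("the flatworm mito preset keeps what the default removes", {
  genes <- c("g1", "g2", "mt-1")
  counts <- rbind(c25 = c(40, 35, 25), keepme = c(60, 40, 0))  # 25% mito
  cm <- count_matrix(counts, rownames(counts), genes,
                     mito_flags = genes == "mt-1")
  oyster <- filter_cells(cm, qc_params(min_genes_per_cell = 1))
  expect_false("c25" %in% oyster$counts$cell_ids)
  flatworm <- filter_cells(cm, qc_params(min_genes_per_cell = 1,
                                         max_mito_fraction = 0.30))
  expect_true("c25" %in% flatworm$counts$cell_ids)
})

test_that("filter_cells is idempotent and drops emptied genes", {
  sim <- simulate_counts(sim_spec(seed = 4, n_cells = 80, n_genes = 300,
                                  n_clusters = 2, markers_per_cluster = 20,
                                  mito_high_frac = 0.2))
  once <- filter_cells(sim$counts, qc_params(min_genes_per_cell = 50))
  expect_gt(once$report$n_removed_high_mito, 0)
  twice <- filter_cells(once$counts, qc_params(min_genes_per_cell = 50))
  expect_identical(as.matrix(twice$counts$counts),
                   as.matrix(once$counts$counts))
  expect_equal(twice$report$n_removed_total, 0L)
})

test_that("normalize_log1p matches the hand-computed value and invariances", {
  cm <- count_matrix(matrix(c(1L, 1L), 1, 2), "c1", c("g1", "g2"))
  em <- normalize_log1p(cm)
  expect_equal(as.numeric(em["c1", ]), rep(log(5001), 2), tolerance = 1e-12)

  # all-zero gene stays zero; doubling a cell's counts changes nothing
  m <- matrix(c(3L, 5L, 0L, 2L, 7L, 0L), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  cm2 <- count_matrix(m, rownames(m), colnames(m))
  em2 <- normalize_log1p(cm2)
  expect_true(all(em2[, "g3"] == 0))
  cm3 <- count_matrix(m * c(2L, 1L), rownames(m), colnames(m))
  expect_equal(as.matrix(normalize_log1p(cm3)), as.matrix(em2),
               tolerance = 1e-12)

  cm0 <- count_matrix(matrix(c(1L, 0L), 2, 1), c("a", "zero"), "g1")
  expect_error(normalize_log1p(cm0), "zero")
})

test_that("select_variable_genes recovers planted high-dispersion genes", {
  nc <- 200; ng <- 1000
  X <- withr::with_seed(99, {
    # background: Poisson genes across a wide mean range; planted: same
    # means but strongly over-dispersed, so they stand off the trend
    mu <- stats::rlnorm(ng, 0, 1)
    mu[1:50] <- stats::runif(50, 1, 5)
    X <- sapply(seq_len(ng), function(g) stats::rpois(nc, mu[g]))
    X[, 1:50] <- sapply(1:50, function(g)
      stats::rnbinom(nc, mu = mu[g], size = 0.3))
    X
  })
  colnames(X) <- sprintf("g%04d", seq_len(ng))
  cm <- count_matrix(X, sprintf("c%03d", seq_len(nc)), colnames(X))
  top <- select_variable_genes(cm, 100)
  expect_true(all(sprintf("g%04d", 1:50) %in% top))

  # constant gene is never selected, even when asking for everything
  X2 <- cbind(X[, 1:20], const = rep(5L, nc))
  cm2 <- count_matrix(X2, cm$cell_ids, colnames(X2))
  expect_warning(all_g <- select_variable_genes(cm2, 50), "nonzero variance")
  expect_false("const" %in% all_g)
})

test_that("embed_pca is exact on a plane, sign-stable and duplicates-safe", {
  withr::with_seed(7, {
    basis <- matrix(stats::rnorm(20 * 2), 2, 20)
    scores2d <- matrix(stats::rnorm(50 * 2), 50, 2)
    X <- scores2d %*% basis
  })
  rownames(X) <- sprintf("c%02d", 1:50)
  colnames(X) <- sprintf("g%02d", 1:20)
  emb <- embed_pca(X, colnames(X), d = 2, clip = 100)
  # the scaled data have rank 2, so a 2-component projection is lossless:
  # all pairwise distances are preserved exactly
  expect_equal(as.matrix(dist(emb)), as.matrix(dist(scale(X))),
               tolerance = 1e-9, ignore_attr = TRUE)

  # flipping the input sign flips coordinates under the fixed-sign rule
  emb_neg <- embed_pca(-X, colnames(X), d = 2, clip = 100)
  expect_equal(emb_neg, -emb, tolerance = 1e-9)

  # identical cells embed identically
  X2 <- rbind(X, X[1, , drop = FALSE]); rownames(X2)[51] <- "dup"
  emb2 <- embed_pca(X2, colnames(X2), d = 2, clip = 100)
  expect_equal(unname(emb2["dup", ]), unname(emb2["c01", ]))

  expect_error(embed_pca(X, colnames(X), d = 25), "exceeds")
})

test_that("initial_clusters separates blobs, refines at high resolution, and is seeded", {
  blobs <- make_blobs(n_per = 50, sep = 12, seed = 3)
  lab1 <- initial_clusters(blobs$coords, resolution = 1, k_neighbors = 15,
                           seed = 0)
  expect_equal(length(unique(lab1)), 2L)
  # the two clusters coincide with the two blobs
  expect_true(all(rowSums(table(lab1, blobs$truth) > 0) == 1))

  lab1b <- initial_clusters(blobs$coords, resolution = 1, k_neighbors = 15,
                            seed = 0)
  expect_identical(lab1, lab1b)

  lab10 <- initial_clusters(blobs$coords, resolution = 10, k_neighbors = 15,
                            seed = 0)
  expect_gte(length(unique(lab10)), 2L)
  # over-clustering refines the blobs but never straddles them
  tab <- table(lab10, blobs$truth)
  expect_true(all(rowSums(tab > 0) == 1))

  expect_error(initial_clusters(blobs$coords[1:10, ], k_neighbors = 20),
               "k_neighbors")
})
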