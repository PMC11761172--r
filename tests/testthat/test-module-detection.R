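test_that("the dynamic cut recovers planted block counts", {
  co <- generate_cohort(n_genes = 120L, k_modules = 3L, module_size = 40L,
                        within_r = 0.9, n_diff = 0L, seed = 5)
  expect_equal(dht_module_count(co$em$values), 3L)
  # size floor: 50 genes cannot hold two modules of 30
  co2 <- generate_cohort(n_genes = 50L, k_modules = 1L, module_size = 40L,
                         within_r = 0.9, n_diff = 0L, seed = 5)
  expect_warning(k2 <- dht_module_count(co2$em$values), "cannot be split")
  expect_equal(k2, 1L)
})

test_that("k-means assignment separates, degenerates and converges", {
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
              dimnames = list(paste0("g", 1:4), NULL))
  p <- kmeans_assign(X, 2, seed = 1)
  expect_equal(p$module_of[["g1"]], p$module_of[["g2"]])
  expect_equal(p$module_of[["g3"]], p$module_of[["g4"]])
  expect_false(p$module_of[["g1"]] == p$module_of[["g3"]])
  p1 <- kmeans_assign(X, 1, seed = 1)
  expect_equal(unname(p1$module_of), rep(1L, 4))
  pn <- kmeans_assign(X, 4, seed = 1)
  expect_equal(sort(unname(pn$module_of)), 1:4)
  expect_equal(attr(pn, "wss"), 0)
  expect_error(kmeans_assign(X, 5, seed = 1), "exceeds")
  # the within-cluster objective never increases across iterations
  set.seed(11)
  Xr <- matrix(rnorm(60 * 4), 60, 4,
               dimnames = list(paste0("g", 1:60), NULL))
  pr <- kmeans_assign(Xr, 3, seed = 2)
  expect_true(all(diff(attr(pr, "wss_trace")) <= 1e-9))
  # determinism under a fixed seed
  expect_identical(kmeans_assign(Xr, 3, seed = 2)$module_of, pr$module_of)
})

test_that("hybrid clustering recovers planted embeddings and degenerates", {
  bl <- make_blobs(k = 3, per = 40, seed = 21)
  p <- hcm(bl$X, seed = 3)
  expect_equal(p$k, 3L)
  ari <- deepgcfs:::adjusted_rand_index(unname(p$module_of), bl$truth)
  expect_gte(ari, 0.9)
  # label-permutation stability across seeds on well-separated blobs
  p2 <- hcm(bl$X, seed = 77)
  expect_equal(deepgcfs:::adjusted_rand_index(unname(p$module_of),
                                              unname(p2$module_of)), 1)
  # row-permutation invariance (up to relabeling)
  perm <- sample(nrow(bl$X))
  p3 <- hcm(bl$X[perm, ], seed = 3)
  expect_equal(deepgcfs:::adjusted_rand_index(
    unname(p3$module_of[rownames(bl$X)]), unname(p$module_of)), 1)
  # all-identical rows collapse to one module
  Zc <- matrix(1, 70, 4, dimnames = list(paste0("g", 1:70), NULL))
  expect_equal(hcm(Zc)$k, 1L)
})

test_that("validity indices equal the brute-force oracle", {
  # two pure pairs: zero intra-cluster spread
  X <- matrix(c(0, 0, 10, 10), ncol = 1,
              dimnames = list(paste0("g", 1:4), NULL))
  p <- module_partition(rownames(X), c(1, 1, 2, 2))
  ix <- clustering_indices(X, p)
  expect_equal(ix$SI, 1)
  expect_equal(ix$DBI, 0)
  expect_error(clustering_indices(X, module_partition(rownames(X),
                                                      rep(1, 4))),
               "k = 1")
  # random instances
  set.seed(13)
  for (rep in 1:5) {
    Xr <- matrix(rnorm(40 * 3), 40, 3,
                 dimnames = list(paste0("g", 1:40), NULL))
    lab <- sample(1:3, 40, replace = TRUE)
    lab[1:3] <- 1:3  # every cluster non-empty
    pr <- module_partition(rownames(Xr), lab)
    got <- clustering_indices(Xr, pr)
    want <- oracle_indices(Xr, lab)
    expect_equal(got$SI, want$SI, tolerance = 1e-8)
    expect_equal(got$CHI, want$CHI, tolerance = 1e-8)
    expect_equal(got$DBI, want$DBI, tolerance = 1e-8)
  }
  # degrading a perfect partition lowers the silhouette
  bl <- make_blobs(k = 2, per = 15, d = 3, seed = 31)
  good <- module_partition(rownames(bl$X), bl$truth)
  bad_lab <- bl$truth; bad_lab[1] <- 2
  bad <- module_partition(rownames(bl$X), bad_lab)
  expect_lt(clustering_indices(bl$X, bad)$SI,
            clustering_indices(bl$X, good)$SI)
})

test_that("the internal adjusted Rand index agrees with mclust", {
  set.seed(17)
  for (rep in 1:5) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(deepgcfs:::adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("the baseline benchmark reports all methods at the same k", {
  bl <- make_blobs(k = 3, per = 30, seed = 41)
  p <- hcm(bl$X, seed = 1)
  bench <- module_benchmark(bl$X, p, seed = 1)
  expect_setequal(bench$method,
                  c("hcm", "kmeans", "hierarchical", "spectral", "fcm"))
  expect_true(all(is.finite(bench$SI)))
  # on clean blobs the hybrid method should be at or near the best SI
  expect_gte(bench$SI[bench$method == "hcm"], max(bench$SI) - 0.05)
})
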