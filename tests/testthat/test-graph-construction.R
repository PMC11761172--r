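test_that("Pearson similarity reproduces hand-computed correlations", {
  em <- make_em(rbind(v = c(1, 2, 3), u = c(2, 4, 6), w = c(6, 4, 2)))
  s <- pearson_similarity(em)
  expect_equal(s$r["v", "u"], 1)
  expect_equal(s$r["v", "w"], -1)
  # (1,2,3,4) vs (1,3,2,4): covariance 4/3, each sd sqrt(5/3) -> r = 0.8
  em2 <- make_em(rbind(a = 1:4, b = c(1, 3, 2, 4)))
  expect_equal(pearson_similarity(em2)$r["a", "b"], 0.8)
  expect_equal(diag(s$r), rep(1, 3), ignore_attr = TRUE)
  expect_lt(max(abs(s$r - t(s$r))), 1e-12)
  # zero-variance genes are rejected with a pointer to the filter
  em3 <- make_em(rbind(a = c(1, 1, 1), b = c(1, 2, 3)))
  expect_error(pearson_similarity(em3), "filter_genes")
})

test_that("no-isolate threshold equals the exhaustive scan", {
  r <- matrix(c(1, 0.9, 0.2, 0.9, 1, 0.5, 0.2, 0.5, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  sim <- structure(list(gene_ids = letters[1:3], r = r),
                   class = "similarity_matrix")
  expect_equal(max_no_isolate_threshold(sim), 0.5)
  # all pairs perfectly correlated
  em <- make_em(rbind(a = 1:4, b = 2 * (1:4), c = 1:4 + 5))
  expect_equal(max_no_isolate_threshold(pearson_similarity(em)), 1)
  # random instances against the brute-force oracle
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:20, 1)
    em <- make_em(matrix(rnorm(n * 6), n, 6))
    sim <- pearson_similarity(em)
    expect_equal(max_no_isolate_threshold(sim), oracle_threshold(sim$r))
  }
})

test_that("pruning keeps edges at or above the threshold", {
  r <- matrix(c(1, 0.9, 0.2, 0.9, 1, 0.5, 0.2, 0.5, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  sim <- structure(list(gene_ids = letters[1:3], r = r),
                   class = "similarity_matrix")
  g <- prune_graph(sim, 0.5)
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(paste(g$edges$from, g$edges$to), c("a b", "b c"))
  expect_equal(sort(g$edges$weight), c(0.5, 0.9))
  # auto threshold leaves no isolated node
  t_auto <- max_no_isolate_threshold(sim)
  ga <- prune_graph(sim, t_auto)
  deg <- table(factor(c(ga$edges$from, ga$edges$to), levels = ga$nodes))
  expect_true(all(deg >= 1))
  # edge count is non-increasing in t
  set.seed(7)
  em <- make_em(matrix(rnorm(10 * 8), 10, 8))
  sim2 <- pearson_similarity(em)
  counts <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(t)
    nrow(prune_graph(sim2, t)$edges))
  expect_true(all(diff(counts) <= 0))
  # retained non-positive weights are an error
  expect_error(prune_graph(sim2, -0.5), "non-positive")
})

test_that("graph merging averages shared edges and halves unique ones", {
  gp <- toy_graph(list(c("a", "b", 0.6), c("b", "c", 0.4)))
  gs <- toy_graph(list(c("a", "b", 0.8), c("a", "c", 1.0)))
  m <- merge_graphs(gp, gs)
  w <- setNames(m$edges$weight, paste(m$edges$from, m$edges$to))
  expect_equal(w[["a b"]], 0.7)   # present in both: mean
  expect_equal(w[["b c"]], 0.2)   # co-expression only: half
  expect_equal(w[["a c"]], 0.5)   # prior only: half
  # symmetry
  m2 <- merge_graphs(gs, gp)
  expect_identical(m$edges, m2$edges)
  # union edge count on random toy graphs
  set.seed(9)
  for (rep in 1:10) {
    nodes <- paste0("n", 1:8)
    pick <- function() {
      pairs <- t(combn(nodes, 2))
      idx <- sample(nrow(pairs), sample(3:12, 1))
      gene_graph(data.frame(from = pairs[idx, 1], to = pairs[idx, 2],
                            weight = runif(length(idx), 0.1, 1)))
    }
    g1 <- pick(); g2 <- pick()
    mm <- merge_graphs(g1, g2)
    u <- union(paste(g1$edges$from, g1$edges$to),
               paste(g2$edges$from, g2$edges$to))
    expect_equal(nrow(mm$edges), length(u))
  }
})

test_that("an empty prior halves every co-expression weight", {
  em <- make_em(matrix(rnorm(8 * 6), 8, 6))
  sim <- pearson_similarity(em)
  t <- max(0.05, max_no_isolate_threshold(sim))
  gp <- prune_graph(sim, t)
  empty <- gene_graph(NULL, nodes = gp$nodes)
  m <- merge_graphs(gp, empty)
  expect_equal(m$edges$weight, gp$edges$weight / 2)
})
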