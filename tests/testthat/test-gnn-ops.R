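test_that("edge-weight normalization yields convex weights", {
  g <- toy_graph(list(c("a", "b", 0.2), c("a", "c", 0.3), c("a", "d", 0.5),
                      c("b", "c", 0.4)))
  w <- normalize_edge_weights(g, "a", c("b", "c", "d"))
  expect_equal(unname(w), c(0.2, 0.3, 0.5))
  expect_equal(normalize_edge_weights(g, "b", "c"), c(c = 1))
  w2 <- normalize_edge_weights(g, "a", c("b", "c"))
  expect_equal(unname(w2), c(0.4, 0.6))
  expect_length(normalize_edge_weights(g, "d", character(0)), 0)
  # property: sums to one within 1e-12 on random neighborhoods
  set.seed(3)
  for (rep in 1:200) {
    k <- sample(1:8, 1)
    ww <- runif(k, 0.01, 2)
    nb <- paste0("n", seq_len(k))
    gg <- gene_graph(data.frame(from = "hub", to = nb, weight = ww))
    expect_lt(abs(sum(normalize_edge_weights(gg, "hub", nb)) - 1), 1e-12)
  }
})

test_that("aggregation is the weighted mean and stays inside input bounds", {
  H <- rbind(a = c(0, 0), b = c(2, 4))
  expect_equal(aggregate_neighbors(H, c(b = 1)), c(2, 4))
  expect_equal(aggregate_neighbors(H, c(a = 0.5, b = 0.5)), c(1, 2))
  expect_equal(aggregate_neighbors(H, setNames(numeric(0), character(0))),
               c(0, 0))
  set.seed(4)
  for (rep in 1:50) {
    k <- sample(2:6, 1); d <- sample(2:5, 1)
    H <- matrix(rnorm(k * d), k, d,
                dimnames = list(paste0("n", 1:k), NULL))
    w <- runif(k); w <- w / sum(w); names(w) <- rownames(H)
    got <- aggregate_neighbors(H, w)
    brute <- sapply(seq_len(d), function(j) sum(w * H[, j]))
    expect_lt(max(abs(got - brute)), 1e-12)
    expect_true(all(got >= apply(H, 2, min) - 1e-12))
    expect_true(all(got <= apply(H, 2, max) + 1e-12))
  }
})

test_that("layer forward applies the linear map, ReLU and eval determinism", {
  set.seed(1)
  lay0 <- gnn_layer(4, 3, dropout = 0.5, init = matrix(0, 3, 4))
  expect_equal(layer_forward(c(1, 2), c(3, 4), lay0), c(0, 0, 0))
  layn <- gnn_layer(4, 3, init = matrix(-1, 3, 4))
  expect_equal(layer_forward(c(1, 2), c(3, 4), layn), c(0, 0, 0))
  lay <- gnn_layer(4, 3, dropout = 0.5)
  o1 <- layer_forward(c(1, -2), c(0.5, 1), lay, training = FALSE)
  o2 <- layer_forward(c(1, -2), c(0.5, 1), lay, training = FALSE)
  expect_identical(o1, o2)
  expect_error(layer_forward(c(1, 2, 3), c(1, 2), lay), "ncol")
})

test_that("edge batches balance positives and negatives without leakage", {
  tri <- toy_graph(list(c("a", "b", 1), c("b", "c", 1), c("a", "c", 1)))
  expect_error(sample_edge_batch(tri, gnn_config()), "complete")
  path <- toy_graph(list(c("a", "b", 1), c("b", "c", 1)))
  set.seed(2)
  b <- sample_edge_batch(path, gnn_config(edge_batch_size = 1))
  expect_equal(sort(as.vector(b$negatives)), c("a", "c"))
  expect_equal(nrow(b$message_graph$edges), 1L)
  # the batch positive is excluded from the message graph
  pos_key <- paste(b$positives[, 1], b$positives[, 2])
  msg_keys <- paste(b$message_graph$edges$from, b$message_graph$edges$to)
  expect_false(pos_key %in% msg_keys)
  # positive sampling is uniform over edges (frequency within 3 sigma)
  g5 <- toy_graph(list(c("a", "b", 1), c("b", "c", 2), c("c", "d", 0.5),
                       c("d", "e", 1), c("a", "e", 3)))
  set.seed(5)
  draws <- 2000
  counts <- table(unlist(replicate(draws, {
    bb <- sample_edge_batch(g5, gnn_config(edge_batch_size = 1))
    paste(bb$positives[, 1], bb$positives[, 2])
  }, simplify = FALSE)))
  expect_length(counts, 5L)
  p <- 1 / 5
  sigma <- sqrt(draws * p * (1 - p))
  expect_true(all(abs(counts - draws * p) <= 3 * sigma))
})

test_that("link loss matches the double-loop oracle and its closed forms", {
  # all-zero embeddings: every probability is 1/2, loss = 2 ln 2
  Z0 <- matrix(0, 4, 3, dimnames = list(letters[1:4], NULL))
  batch <- list(positives = cbind("a", "b"), negatives = cbind("c", "d"))
  expect_equal(link_loss(Z0, batch), 2 * log(2))
  # saturated logits drive the loss to zero
  Zbig <- rbind(a = c(10, 0), b = c(10, 0), c = c(10, 0), d = c(-10, 0))
  batch2 <- list(positives = cbind("a", "b"), negatives = cbind("c", "d"))
  expect_lt(link_loss(Zbig, batch2), 1e-6)
  # random instances vs oracle
  set.seed(6)
  for (rep in 1:10) {
    Z <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(paste0("n", 1:6), NULL))
    pos <- cbind(paste0("n", c(1, 2, 3)), paste0("n", c(2, 3, 4)))
    neg <- cbind(paste0("n", c(1, 5)), paste0("n", c(6, 6)))
    expect_equal(link_loss(Z, list(positives = pos, negatives = neg)),
                 oracle_link_loss(Z, pos, neg), tolerance = 1e-8)
  }
})

test_that("reconstruction loss matches the all-ordered-pairs oracle", {
  Z0 <- matrix(0, 2, 3, dimnames = list(c("a", "b"), NULL))
  g0 <- gene_graph(NULL, nodes = c("a", "b"))
  expect_equal(reconstruction_loss(Z0, g0), 2 * log(2))
  # embeddings that reproduce the adjacency drive the loss toward zero
  g1 <- toy_graph(list(c("a", "b", 1)))
  g1 <- gene_graph(g1$edges, nodes = c("a", "b", "c"))
  Zfit <- rbind(a = c(5, 1), b = c(5, 1), c = c(0, -40))
  expect_lt(reconstruction_loss(Zfit, g1), 1e-4)
  set.seed(8)
  for (rep in 1:10) {
    nodes <- paste0("n", 1:5)
    pairs <- t(combn(nodes, 2))
    idx <- sample(nrow(pairs), 4)
    g <- gene_graph(data.frame(from = pairs[idx, 1], to = pairs[idx, 2],
                               weight = 1), nodes = nodes)
    Z <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(nodes, NULL))
    expect_equal(reconstruction_loss(Z, g), oracle_rec_loss(Z, g),
                 tolerance = 1e-8)
  }
})

test_that("total loss is the weighted sum of its parts", {
  expect_equal(total_loss(0.5, 1.5), 2)
  expect_equal(total_loss(3.2, 0), 3.2)
  cfg_rec <- gnn_config(loss_weights = c(0, 1))
  expect_equal(total_loss(7, 2.5, cfg_rec), 2.5)
})
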