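# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately naive (double loops, exhaustive scans) so it cannot
# share a bug with the vectorized implementations it checks.

make_em <- function(values, labels = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, labels = labels)
}

toy_graph <- function(edges) {
  # edges: list of c(from, to, weight)
  df <- do.call(rbind, lapply(edges, function(e)
    data.frame(from = e[[1]], to = e[[2]], weight = as.numeric(e[[3]]),
               stringsAsFactors = FALSE)))
  gene_graph(df)
}

# exhaustive scan for the largest no-isolate pruning threshold
oracle_threshold <- function(r) {
  n <- nrow(r)
  diag(r) <- NA
  cands <- sort(unique(as.vector(r[!is.na(r)])), decreasing = TRUE)
  for (t in cands) {
    deg <- sapply(seq_len(n), function(i) sum(r[i, -i] >= t, na.rm = TRUE))
    if (all(deg >= 1)) return(t)
  }
  min(cands)
}

oracle_link_loss <- function(Z, pos, neg) {
  bce <- function(pairs, target) {
    vals <- numeric(nrow(pairs))
    for (q in seq_len(nrow(pairs))) {
      phi <- sum(Z[pairs[q, 1], ] * Z[pairs[q, 2], ])
      p <- 1 / (1 + exp(-phi))
      p <- min(max(p, 1e-7), 1 - 1e-7)
      vals[q] <- if (target == 1) -log(p) else -log(1 - p)
    }
    mean(vals)
  }
  bce(pos, 1) + bce(neg, 0)
}

oracle_rec_loss <- function(Z, g) {
  nodes <- g$nodes
  key <- paste(g$edges$from, g$edges$to)
  total <- 0
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i == j) next
      a <- as.integer(paste(min(nodes[i], nodes[j]),
                            max(nodes[i], nodes[j])) %in% key)
      phi <- sum(Z[nodes[i], ] * Z[nodes[j], ])
      p <- 1 / (1 + exp(-phi))
      p <- min(max(p, 1e-7), 1 - 1e-7)
      total <- total - a * log(p) - (1 - a) * log(1 - p)
    }
  }
  total
}

oracle_indices <- function(X, lab) {
  n <- nrow(X)
  k <- max(lab)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i] & seq_len(n) != i)
    if (length(own) == 0) { sil[i] <- 0; next }
    a <- mean(sapply(own, function(j) d(i, j)))
    b <- Inf
    for (m in setdiff(seq_len(k), lab[i])) {
      mm <- mean(sapply(which(lab == m), function(j) d(i, j)))
      b <- min(b, mm)
    }
    sil[i] <- (b - a) / max(a, b)
  }
  cent <- t(sapply(seq_len(k), function(m)
    colMeans(X[lab == m, , drop = FALSE])))
  grand <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (m in seq_len(k))
    ssb <- ssb + sum(lab == m) * sum((cent[m, ] - grand)^2)
  for (i in seq_len(n)) ssw <- ssw + sum((X[i, ] - cent[lab[i], ])^2)
  chi <- (ssb / (k - 1)) / (ssw / (n - k))
  s <- sapply(seq_len(k), function(m)
    mean(sapply(which(lab == m), function(i) sqrt(sum((X[i, ] - cent[m, ])^2)))))
  dbi <- mean(sapply(seq_len(k), function(i)
    max(sapply(setdiff(seq_len(k), i), function(j)
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))))))
  list(SI = mean(sil), CHI = chi, DBI = dbi)
}

# AUC by counting concordant score pairs, ties worth one half
oracle_auc <- function(scores, y) {
  y <- factor(as.vector(y))
  pos <- which(y == levels(y)[2])
  neg <- which(y == levels(y)[1])
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Welch two-sided t-test p-value from the textbook formulas
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# planted blob embedding: k well-separated gaussian clusters in d dims
make_blobs <- function(k = 3, per = 40, d = 8, sep = 10, sd = 0.5,
                       seed = 1) {
  set.seed(seed)
  cent <- matrix(rnorm(k * d), k, d) * sep
  X <- do.call(rbind, lapply(seq_len(k), function(m)
    matrix(rnorm(per * d, sd = sd), per, d) +
      matrix(cent[m, ], per, d, byrow = TRUE)))
  rownames(X) <- paste0("g", seq_len(k * per))
  list(X = X, truth = rep(seq_len(k), each = per))
}
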