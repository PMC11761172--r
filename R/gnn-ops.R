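## Elementary operations of the weighted-aggregation GNN. These are the
## building blocks train_embeddings() composes; they are exported so each
## contract can be exercised in isolation.

.gnn_state <- new.env(parent = emptyenv())

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp_prob <- function(p, eps = 1e-7) {
  if (any(p < eps | p > 1 - eps)) {
    if (!isTRUE(.gnn_state$clamp_noted)) {
      message("link probabilities clamped to [1e-7, 1 - 1e-7]")
      .gnn_state$clamp_noted <- TRUE
    }
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  p
}

#' Normalize the weights of a node's sampled edges
#'
#' Divides each sampled edge weight by the sum over the sampled neighbors so
#' the weights form a convex combination (they sum to 1). An empty neighbor
#' set returns an empty map; aggregation then falls back to the zero vector
#' and the node relies on its self state.
#'
#' @param g a [gene_graph()] with strictly positive weights.
#' @param node a gene id in `g`.
#' @param neighbors character vector of sampled neighbor ids (must be actual
#'   neighbors of `node`).
#' @return named numeric vector of normalized weights summing to 1.
#' @export
normalize_edge_weights <- function(g, node, neighbors) {
  stopifnot(inherits(g, "gene_graph"), node %in% g$nodes)
  if (length(neighbors) == 0L) return(setNames(numeric(0), character(0)))
  e <- g$edges
  sel <- (e$from == node & e$to %in% neighbors) |
         (e$to == node & e$from %in% neighbors)
  other <- ifelse(e$from[sel] == node, e$to[sel], e$from[sel])
  w <- setNames(e$weight[sel], other)
  if (!all(neighbors %in% names(w)))
    stop("some sampled neighbors are not adjacent to ", node)
  w <- w[neighbors]
  w / sum(w)
}

#' Weighted mean aggregation of neighbor states
#'
#' Returns the convex combination of the neighbors' previous-layer vectors
#' under normalized weights; an empty neighborhood yields the zero vector.
#'
#' @param h_prev numeric matrix of previous-layer states, rows named by node
#'   id (a single named list of vectors is also accepted).
#' @param weights named normalized weights as from
#'   [normalize_edge_weights()].
#' @return the aggregated numeric vector.
#' @export
aggregate_neighbors <- function(h_prev, weights) {
  if (is.list(h_prev) && !is.matrix(h_prev))
    h_prev <- do.call(rbind, h_prev)
  if (length(weights) == 0L) return(numeric(ncol(h_prev)))
  stopifnot(all(names(weights) %in% rownames(h_prev)),
            abs(sum(weights) - 1) < 1e-8)
  drop(weights %*% h_prev[names(weights), , drop = FALSE])
}

#' Construct one trainable GNN layer
#'
#' @param w_in input width (self state plus aggregated state, i.e. twice the
#'   previous layer width).
#' @param w_out output width.
#' @param dropout dropout probability.
#' @param batch_norm logical.
#' @param init `"glorot"` uniform initialization, or a matrix to use as-is.
#' @return a list with the weight matrix `W` (`w_out x w_in`), batch-norm
#'   parameters and running statistics.
#' @export
gnn_layer <- function(w_in, w_out, dropout = 0, batch_norm = TRUE,
                      init = "glorot") {
  W <- if (is.matrix(init)) {
    stopifnot(nrow(init) == w_out, ncol(init) == w_in)
    init
  } else {
    lim <- sqrt(6 / (w_in + w_out))
    matrix(runif(w_out * w_in, -lim, lim), w_out, w_in)
  }
  list(W = W, dropout = dropout, batch_norm = isTRUE(batch_norm),
       gamma = rep(1, w_out), beta = rep(0, w_out),
       run_mean = rep(0, w_out), run_var = rep(1, w_out))
}

## Batch-norm forward over rows; returns normalized matrix plus cache.
bn_forward <- function(x, layer, training, momentum = 0.9, eps = 1e-5) {
  if (training && nrow(x) > 1L) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu)^2)
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  xhat <- sweep(sweep(x, 2L, mu), 2L, sqrt(v + eps), "/")
  out <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
  list(out = out, xhat = xhat, mu = mu, var = v, eps = eps,
       new_run_mean = momentum * layer$run_mean + (1 - momentum) * mu,
       new_run_var = momentum * layer$run_var + (1 - momentum) * v)
}

#' Forward pass through one GNN layer
#'
#' Computes `ReLU(W %*% c(h_self, h_agg))`; in training mode batch
#' normalization (batch statistics) and inverted dropout are applied on top,
#' in evaluation mode the output is deterministic (running statistics, no
#' dropout).
#'
#' @param h_self self state: vector, or matrix with one row per node.
#' @param h_agg aggregated neighbor state of matching shape.
#' @param layer a [gnn_layer()].
#' @param training logical.
#' @return vector or matrix of layer outputs (width `nrow(layer$W)`).
#' @export
layer_forward <- function(h_self, h_agg, layer, training = FALSE) {
  vec_in <- is.null(dim(h_self))
  if (vec_in) {
    h_self <- matrix(h_self, 1L)
    h_agg <- matrix(h_agg, 1L)
  }
  stopifnot(ncol(h_self) == ncol(h_agg),
            ncol(layer$W) == ncol(h_self) + ncol(h_agg))
  pre <- cbind(h_self, h_agg) %*% t(layer$W)
  out <- pmax(pre, 0)
  if (training) {
    if (layer$batch_norm) out <- bn_forward(out, layer, training = TRUE)$out
    if (layer$dropout > 0) {
      mask <- matrix(runif(length(out)) >= layer$dropout, nrow(out))
      out <- out * mask / (1 - layer$dropout)
    }
  } else if (layer$batch_norm) {
    out <- bn_forward(out, layer, training = FALSE)$out
  }
  if (vec_in) drop(out) else out
}

#' Sample a balanced batch of positive and negative node pairs
#'
#' Positives are drawn uniformly without replacement from the edge set;
#' negatives are drawn uniformly from non-adjacent node pairs by rejection
#' sampling. The batch's positive edges are removed from the returned
#' `message_graph` so that message passing cannot leak the edges being
#' predicted.
#'
#' @param g a [gene_graph()] with at least one edge and one non-edge.
#' @param cfg a [gnn_config()]; uses `edge_batch_size` and `neg_per_pos`.
#' @return list with `positives`, `negatives` (two-column character
#'   matrices) and `message_graph`.
#' @export
sample_edge_batch <- function(g, cfg) {
  ne <- n_edges(g)
  n <- length(g$nodes)
  stopifnot(ne >= 1L)
  if (ne >= n * (n - 1) / 2)
    stop("graph is complete: no negative pairs exist; use a lower pruning threshold")
  npos <- min(cfg$edge_batch_size, ne)
  pos_idx <- sample.int(ne, npos)
  positives <- cbind(g$edges$from[pos_idx], g$edges$to[pos_idx])
  edge_keys <- paste(g$edges$from, g$edges$to, sep = "\r")
  nneg <- max(1L, round(cfg$neg_per_pos * npos))
  neg_from <- character(nneg)
  neg_to <- character(nneg)
  got <- 0L
  guard <- 0L
  while (got < nneg) {
    guard <- guard + 1L
    if (guard > 1000L * nneg)
      stop("negative sampling failed: graph too dense; use a lower pruning threshold")
    i <- sample.int(n, 1L)
    j <- sample.int(n, 1L)
    if (i == j) next
    a <- g$nodes[min(i, j)]
    b <- g$nodes[max(i, j)]
    if (paste(a, b, sep = "\r") %in% edge_keys) next
    got <- got + 1L
    neg_from[got] <- a
    neg_to[got] <- b
  }
  msg_edges <- g$edges[-pos_idx, , drop = FALSE]
  list(positives = positives,
       negatives = cbind(neg_from, neg_to),
       message_graph = gene_graph(if (nrow(msg_edges)) msg_edges else NULL,
                                  nodes = g$nodes))
}

pair_logits <- function(Z, pairs) {
  i <- match(pairs[, 1L], rownames(Z))
  j <- match(pairs[, 2L], rownames(Z))
  if (anyNA(i) || anyNA(j)) stop("batch node missing from embedding matrix")
  rowSums(Z[i, , drop = FALSE] * Z[j, , drop = FALSE])
}

#' Balanced link-prediction cross-entropy loss
#'
#' The affiliation score of a pair is the embedding dot product; its sigmoid
#' is the predicted edge probability. The loss is the mean negative
#' log-probability over positives plus the mean negative log-probability of
#' absence over negatives (balanced binary cross-entropy). Probabilities are
#' clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param Z embedding matrix with gene-id rownames.
#' @param batch a [sample_edge_batch()] result (or any list with
#'   `positives` / `negatives` two-column matrices).
#' @return scalar loss.
#' @export
link_loss <- function(Z, batch) {
  p_pos <- clamp_prob(sigmoid(pair_logits(Z, batch$positives)))
  p_neg <- clamp_prob(sigmoid(pair_logits(Z, batch$negatives)))
  mean(-log(p_pos)) + mean(-log(1 - p_neg))
}

#' Adjacency reconstruction cross-entropy loss
#'
#' Reconstructs the adjacency indicator as `sigmoid(Z %*% t(Z))` and sums the
#' per-pair binary cross-entropy over all ordered pairs i != j (self pairs
#' are excluded: the sigmoid of a squared norm can never predict the zero
#' diagonal). For graphs above `max_full_n` nodes the sum is estimated from
#' `50 * |E|` uniformly sampled ordered pairs and rescaled; the estimate is
#' flagged with a message.
#'
#' @param Z embedding matrix with gene-id rownames covering all nodes of `g`.
#' @param g a [gene_graph()].
#' @param max_full_n largest node count for exact full-matrix evaluation.
#' @return scalar loss (sum over ordered pairs).
#' @export
reconstruction_loss <- function(Z, g, max_full_n = 5000L) {
  stopifnot(all(g$nodes %in% rownames(Z)))
  n <- length(g$nodes)
  Zg <- Z[g$nodes, , drop = FALSE]
  if (n <= max_full_n) {
    P <- clamp_prob(sigmoid(tcrossprod(Zg)))
    A <- as.matrix(graph_adjacency(g, indicator = TRUE))
    ce <- -A * log(P) - (1 - A) * log(1 - P)
    diag(ce) <- 0
    sum(ce)
  } else {
    n_pairs <- min(50L * n_edges(g), n * (n - 1))
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    A <- graph_adjacency(g, indicator = TRUE)
    a <- A[cbind(i, j)]
    p <- clamp_prob(sigmoid(rowSums(Zg[i, , drop = FALSE] *
                                    Zg[j, , drop = FALSE])))
    message("reconstruction loss estimated from ", length(i),
            " sampled ordered pairs (scaled)")
    sum(-a * log(p) - (1 - a) * log(1 - p)) * (n * (n - 1)) / length(i)
  }
}

#' Combined training loss
#'
#' Weighted sum of the link-prediction and reconstruction terms; the default
#' weights `(1, 1)` give their plain sum.
#'
#' @param l_link link loss value.
#' @param l_rec reconstruction loss value.
#' @param cfg a [gnn_config()].
#' @return scalar total loss.
#' @export
total_loss <- function(l_link, l_rec, cfg = gnn_config()) {
  stopifnot(is.finite(l_link), is.finite(l_rec))
  cfg$loss_weights[["link"]] * l_link + cfg$loss_weights[["rec"]] * l_rec
}
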