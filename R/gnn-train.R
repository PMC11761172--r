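## Training loop for the weighted-aggregation GNN. Written against base
## matrix algebra (plus Matrix for the sparse aggregation operator) with
## manual backpropagation and Adam; the network is small (tens of thousands
## of parameters), so dense linear algebra is the right tool.

## Sparse aggregation operator: row v holds the normalized weights of the
## (sampled) neighbors of v. Rows of isolated nodes are zero.
aggregation_operator <- function(adj, n, fanout = NULL) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (v in seq_len(n)) {
    nb <- adj$neighbors[[v]]
    w <- adj$weights[[v]]
    if (length(nb) == 0L) next
    if (!is.null(fanout) && length(nb) > fanout) {
      pick <- sample.int(length(nb), fanout)
      nb <- nb[pick]; w <- w[pick]
    }
    ii <- c(ii, rep.int(v, length(nb)))
    jj <- c(jj, nb)
    xx <- c(xx, w / sum(w))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

## Forward pass through all layers; returns caches needed for backprop.
gnn_forward <- function(H0, layers, S_list, training, dropout) {
  L <- length(layers)
  cache <- vector("list", L)
  H <- H0
  for (k in seq_len(L)) {
    A <- as.matrix(S_list[[k]] %*% H)
    C <- cbind(H, A)
    pre <- C %*% t(layers[[k]]$W)
    relu <- pmax(pre, 0)
    out <- relu
    bn <- NULL
    if (layers[[k]]$batch_norm) {
      bn <- bn_forward(relu, layers[[k]], training = training)
      out <- bn$out
    }
    mask <- NULL
    if (training && dropout > 0) {
      mask <- matrix(runif(length(out)) >= dropout, nrow(out))
      out <- out * mask / (1 - dropout)
    }
    cache[[k]] <- list(C = C, pre = pre, bn = bn, mask = mask, H_in = H)
    H <- out
  }
  list(Z = H, cache = cache)
}

## Gradient of the balanced link loss with respect to Z.
link_grad <- function(Z, ip, jp, im, jm) {
  phi_p <- rowSums(Z[ip, , drop = FALSE] * Z[jp, , drop = FALSE])
  phi_n <- rowSums(Z[im, , drop = FALSE] * Z[jm, , drop = FALSE])
  p_p <- clamp_prob(sigmoid(phi_p))
  p_n <- clamp_prob(sigmoid(phi_n))
  loss <- mean(-log(p_p)) + mean(-log(1 - p_n))
  dphi_p <- (p_p - 1) / length(p_p)
  dphi_n <- p_n / length(p_n)
  idx <- c(ip, jp, im, jm)
  contrib <- rbind(dphi_p * Z[jp, , drop = FALSE],
                   dphi_p * Z[ip, , drop = FALSE],
                   dphi_n * Z[jm, , drop = FALSE],
                   dphi_n * Z[im, , drop = FALSE])
  agg <- rowsum(contrib, group = idx)
  dZ <- matrix(0, nrow(Z), ncol(Z))
  rows <- as.integer(rownames(agg))
  dZ[rows, ] <- agg
  list(loss = loss, dZ = dZ)
}

## Loss and gradient of the full adjacency reconstruction term.
rec_grad <- function(Z, A) {
  P <- sigmoid(tcrossprod(Z))
  Pc <- pmin(pmax(P, 1e-7), 1 - 1e-7)
  ce <- -A * log(Pc) - (1 - A) * log(1 - Pc)
  diag(ce) <- 0
  G <- P - A
  diag(G) <- 0
  list(loss = sum(ce), dZ = 2 * (G %*% Z))
}

bn_backward <- function(dout, bn, gamma) {
  N <- nrow(dout)
  dgamma <- colSums(dout * bn$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, gamma, "*")
  inv_sd <- 1 / sqrt(bn$var + bn$eps)
  t1 <- sweep(dxhat, 2L, colSums(dxhat) / N)
  t2 <- sweep(bn$xhat, 2L, colSums(dxhat * bn$xhat) / N, "*")
  dx <- sweep(t1 - t2, 2L, inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

adam_step <- function(param, grad, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train GNN node embeddings on a gene graph
#'
#' Runs `cfg$epochs` training steps. Each step samples a balanced edge batch,
#' removes the batch positives from the message graph, samples up to
#' `neighbor_fanout` neighbors per node per layer, runs the forward pass
#' (weighted mean aggregation, concatenation with the self state, linear map,
#' ReLU, batch normalization, dropout) and updates all parameters with Adam
#' on the combined link-prediction + reconstruction loss. The returned
#' embeddings are computed in evaluation mode (full neighborhoods, frozen
#' batch-norm statistics, no dropout), so they are deterministic given the
#' trained parameters; the whole run is deterministic given `cfg$seed`.
#'
#' @param g a [gene_graph()] whose nodes are exactly the genes of `em`.
#' @param em an [expression_matrix()]; the expression profile across samples
#'   is the initial feature vector of each gene node.
#' @param cfg a [gnn_config()].
#' @return an object of class `gene_embedding`: list with `Z` (genes x d,
#'   rownames = gene ids), `loss_history` (data.frame epoch/link/rec/total),
#'   and `config`.
#' @export
train_embeddings <- function(g, em, cfg = gnn_config()) {
  stopifnot(inherits(g, "gene_graph"), inherits(em, "expr_matrix"),
            inherits(cfg, "gnn_config"))
  if (!setequal(g$nodes, em$gene_ids))
    stop("graph nodes and expression genes differ")
  set.seed(cfg$seed)
  n <- length(g$nodes)
  H0 <- em$values[g$nodes, , drop = FALSE]
  d_in <- ncol(H0)
  widths <- c(d_in, cfg$dims)
  layers <- lapply(seq_len(cfg$n_layers), function(k)
    gnn_layer(2L * widths[k], widths[k + 1L], dropout = cfg$dropout,
              batch_norm = cfg$batch_norm))
  A_full <- as.matrix(graph_adjacency(g, indicator = TRUE))
  ei <- match(g$edges$from, g$nodes)
  ej <- match(g$edges$to, g$nodes)
  edge_num <- (pmin(ei, ej) - 1) * n + pmax(ei, ej)
  lw <- cfg$loss_weights
  zero_like <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  opt <- lapply(layers, function(l) list(
    W = list(m = zero_like(l$W), v = zero_like(l$W)),
    gamma = list(m = zero_like(l$gamma), v = zero_like(l$gamma)),
    beta = list(m = zero_like(l$beta), v = zero_like(l$beta))))
  history <- data.frame(epoch = integer(), link = numeric(),
                        rec = numeric(), total = numeric())
  ne <- n_edges(g)
  if (ne < 1L) stop("graph has no edges; cannot train")
  if (ne >= n * (n - 1) / 2)
    stop("graph is complete: no negative pairs; use a lower pruning threshold")

  for (epoch in seq_len(cfg$epochs)) {
    npos <- min(cfg$edge_batch_size, ne)
    pos_idx <- sample.int(ne, npos)
    ip <- match(g$edges$from[pos_idx], g$nodes)
    jp <- match(g$edges$to[pos_idx], g$nodes)
    nneg <- max(1L, round(cfg$neg_per_pos * npos))
    im <- integer(0); jm <- integer(0); guard <- 0L
    while (length(im) < nneg) {
      guard <- guard + 1L
      if (guard > 1000L) stop("negative sampling failed: graph too dense")
      a <- sample.int(n, 2L * nneg, replace = TRUE)
      b <- sample.int(n, 2L * nneg, replace = TRUE)
      ok <- a != b
      lo <- pmin(a, b)[ok]; hi <- pmax(a, b)[ok]
      keep <- !((lo - 1) * n + hi) %in% edge_num
      im <- c(im, lo[keep]); jm <- c(jm, hi[keep])
    }
    im <- im[seq_len(nneg)]; jm <- jm[seq_len(nneg)]
    msg_edges <- g$edges[-pos_idx, , drop = FALSE]
    msg_g <- gene_graph(if (nrow(msg_edges)) msg_edges else NULL,
                        nodes = g$nodes)
    adj <- graph_neighbors(msg_g)
    S_list <- lapply(seq_len(cfg$n_layers), function(k)
      aggregation_operator(adj, n, fanout = cfg$neighbor_fanout))

    fwd <- gnn_forward(H0, layers, S_list, training = TRUE,
                       dropout = cfg$dropout)
    Z <- fwd$Z
    lg <- link_grad(Z, ip, jp, im, jm)
    rg <- rec_grad(Z, A_full)
    tot <- lw[["link"]] * lg$loss + lw[["rec"]] * rg$loss
    if (!is.finite(tot))
      stop(sprintf(
        "training diverged (non-finite loss) at epoch %d; try a smaller learning rate than %g",
        epoch, cfg$learning_rate))
    history[epoch, ] <- list(epoch, lg$loss, rg$loss, tot)

    dH <- lw[["link"]] * lg$dZ + lw[["rec"]] * rg$dZ
    for (k in rev(seq_len(cfg$n_layers))) {
      ck <- fwd$cache[[k]]
      if (!is.null(ck$mask)) dH <- dH * ck$mask / (1 - cfg$dropout)
      dgamma <- NULL; dbeta <- NULL
      if (!is.null(ck$bn)) {
        bb <- bn_backward(dH, ck$bn, layers[[k]]$gamma)
        dH <- bb$dx
        dgamma <- bb$dgamma
        dbeta <- bb$dbeta
      }
      dpre <- dH * (ck$pre > 0)
      dW <- crossprod(dpre, ck$C)
      dC <- dpre %*% layers[[k]]$W
      d_prev <- ncol(ck$H_in)
      dH <- dC[, seq_len(d_prev), drop = FALSE] +
        as.matrix(Matrix::crossprod(S_list[[k]],
                                    dC[, d_prev + seq_len(d_prev),
                                       drop = FALSE]))
      st <- adam_step(layers[[k]]$W, dW, opt[[k]]$W, cfg$learning_rate, epoch)
      layers[[k]]$W <- st$param; opt[[k]]$W <- st$state
      if (!is.null(dgamma)) {
        st <- adam_step(layers[[k]]$gamma, dgamma, opt[[k]]$gamma,
                        cfg$learning_rate, epoch)
        layers[[k]]$gamma <- st$param; opt[[k]]$gamma <- st$state
        st <- adam_step(layers[[k]]$beta, dbeta, opt[[k]]$beta,
                        cfg$learning_rate, epoch)
        layers[[k]]$beta <- st$param; opt[[k]]$beta <- st$state
        layers[[k]]$run_mean <- fwd$cache[[k]]$bn$new_run_mean
        layers[[k]]$run_var <- fwd$cache[[k]]$bn$new_run_var
      }
    }
  }

  # final evaluation-mode pass on the full graph: no neighbor sampling, no
  # dropout, frozen batch-norm statistics
  adj_full <- graph_neighbors(g)
  S_full <- aggregation_operator(adj_full, n, fanout = NULL)
  S_eval <- rep(list(S_full), cfg$n_layers)
  Z <- gnn_forward(H0, layers, S_eval, training = FALSE, dropout = 0)$Z
  rownames(Z) <- g$nodes
  colnames(Z) <- paste0("d", seq_len(ncol(Z)))
  structure(list(Z = Z, gene_ids = g$nodes, loss_history = history,
                 config = cfg, layers = layers),
            class = "gene_embedding")
}

#' @export
print.gene_embedding <- function(x, ...) {
  cat(sprintf("Gene embedding: %d genes x %d dims (%d epochs, final loss %.4g)\n",
              nrow(x$Z), ncol(x$Z), nrow(x$loss_history),
              x$loss_history$total[nrow(x$loss_history)]))
  invisible(x)
}

#' Write embeddings as TSV (gene_id + one column per dimension)
#'
#' @param emb a [train_embeddings()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  df <- data.frame(gene_id = rownames(emb$Z), emb$Z, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
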