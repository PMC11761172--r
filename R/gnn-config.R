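#' Configuration for the graph neural network embedder
#'
#' Defaults follow the reference setup where stated (three layers, dropout
#' 0.5, batch normalization, Adam) and documented package defaults elsewhere
#' (embedding width 64, 300 epochs, 512 positive edges per batch, one
#' negative per positive, neighbor fanout 10, learning rate 1e-3, equal loss
#' weights).
#'
#' @param n_layers number of message-passing layers (>= 1).
#' @param dims integer vector of layer output widths, length `n_layers`; the
#'   last entry is the embedding dimension d. A single value is recycled.
#' @param dropout dropout probability in `[0, 1)`, applied in training only.
#' @param batch_norm logical; apply batch normalization per layer. Batch
#'   statistics are used in training, frozen running averages at evaluation.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs (one edge batch per epoch).
#' @param edge_batch_size positive edges sampled per batch.
#' @param neg_per_pos negatives sampled per positive.
#' @param neighbor_fanout neighbors sampled per node per layer.
#' @param loss_weights length-2 numeric `(link, reconstruction)`; defaults
#'   `(1, 1)` reproduce the plain sum of the two loss terms.
#' @param seed integer RNG seed; the whole training run is deterministic
#'   given the seed.
#' @return an object of class `gnn_config`.
#' @export
gnn_config <- function(n_layers = 3L, dims = 64L, dropout = 0.5,
                       batch_norm = TRUE, learning_rate = 1e-3,
                       epochs = 300L, edge_batch_size = 512L,
                       neg_per_pos = 1, neighbor_fanout = 10L,
                       loss_weights = c(link = 1, rec = 1), seed = 1L) {
  n_layers <- as.integer(n_layers)
  stopifnot(n_layers >= 1L, dropout >= 0, dropout < 1,
            neighbor_fanout >= 1L, all(loss_weights >= 0),
            length(loss_weights) == 2L, learning_rate > 0,
            epochs >= 1L, edge_batch_size >= 1L, neg_per_pos > 0)
  dims <- as.integer(dims)
  if (length(dims) == 1L) dims <- rep(dims, n_layers)
  stopifnot(length(dims) == n_layers, all(dims >= 1L))
  structure(
    list(n_layers = n_layers, dims = dims, dropout = dropout,
         batch_norm = isTRUE(batch_norm), learning_rate = learning_rate,
         epochs = as.integer(epochs),
         edge_batch_size = as.integer(edge_batch_size),
         neg_per_pos = neg_per_pos,
         neighbor_fanout = as.integer(neighbor_fanout),
         loss_weights = setNames(as.numeric(loss_weights), c("link", "rec")),
         seed = as.integer(seed)),
    class = "gnn_config"
  )
}

#' @export
print.gnn_config <- function(x, ...) {
  cat(sprintf(
    "GNN config: %d layers (dims %s), dropout %.2f, batch_norm %s\n",
    x$n_layers, paste(x$dims, collapse = "-"), x$dropout, x$batch_norm))
  cat(sprintf(
    "  Adam lr %g, %d epochs, batch %d pos (x%g neg), fanout %d, loss weights (%g, %g), seed %d\n",
    x$learning_rate, x$epochs, x$edge_batch_size, x$neg_per_pos,
    x$neighbor_fanout, x$loss_weights[1L], x$loss_weights[2L], x$seed))
  invisible(x)
}
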