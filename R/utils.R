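## Internal helpers shared across modules.

#' Derive a stage seed from a global seed
#'
#' Stage seeds are derived by stable string hashing of the stage name so that
#' the randomness of one stage never depends on how often another stage drew
#' from the RNG. The result is a non-negative integer below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage name, e.g. `"embed"`.
#' @return an integer seed.
#' @export
#' @examples
#' stage_seed(7, "embed")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # polynomial rolling hash over the UTF-8 bytes, kept in double precision
  # (< 2^53) and reduced mod a prime below 2^31
  p <- 2147483629
  h <- as.double(seed %% p)
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% p
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Coerce labels to a two-level factor, preserving an existing level order
## (the second level is the positive class throughout the package).
binary_factor <- function(y) {
  y <- if (is.factor(y)) droplevels(y) else factor(as.vector(y))
  y
}

## Stable descending order of scores with ties broken by ascending id.
order_scores <- function(scores, ids) {
  order(-scores, ids, method = "radix")
}

## Natural-log entropy of a discrete label vector.
entropy_nats <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log(p))
}

## Discretized mutual information (nats) between a numeric vector and a
## discrete label. Equal-frequency binning; ties broken deterministically by
## a tiny seeded jitter so the estimator is fixed given the seed.
mutual_information <- function(x, y, n_bins = NULL, seed = 1L) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2L)
  if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(n)))
  ux <- unique(x)
  if (length(ux) <= n_bins) {
    # already discrete at or below the bin budget: use the values as bins
    bx <- match(x, sort(ux))
  } else {
    rng <- local({
      set.seed(as.integer(seed))
      runif(n, -1e-9, 1e-9)
    })
    x <- x + rng * max(1, diff(range(x)))
    bx <- cut(rank(x, ties.method = "first"), breaks = n_bins, labels = FALSE)
  }
  tab <- table(bx, y)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
}

## Adjusted Rand index between two label vectors (used by benchmarking code;
## tests cross-check it against mclust::adjustedRandIndex).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

## Write a data.frame as TSV with a header, no quoting, no row names.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
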