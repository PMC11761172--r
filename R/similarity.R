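#' Pearson similarity between gene expression profiles
#'
#' Computes the full gene-by-gene Pearson correlation matrix across samples.
#' Zero-variance genes make the correlation undefined and are rejected;
#' remove them first with [filter_genes()].
#'
#' @param em an [expression_matrix()] with at least two samples.
#' @return an object of class `similarity_matrix`: list with `gene_ids` and
#'   the symmetric correlation matrix `r` (unit diagonal).
#' @export
pearson_similarity <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (ncol(em$values) < 2L) stop("need at least 2 samples for correlation")
  v <- apply(em$values, 1L, var)
  if (any(v == 0))
    stop(sprintf(
      "%d zero-variance gene(s) (e.g. %s): correlation undefined; apply filter_genes() first",
      sum(v == 0), em$gene_ids[which(v == 0)[1L]]))
  r <- cor(t(em$values))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(gene_ids = em$gene_ids, r = r), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Similarity matrix: %d genes\n", length(x$gene_ids)))
  invisible(x)
}

#' Largest pruning threshold that leaves no isolated gene
#'
#' The co-expression graph is pruned by deleting edges with correlation below
#' a threshold; this returns the largest threshold t such that every gene
#' still has at least one incident edge with r >= t, i.e.
#' `min_i max_{j != i} r[i, j]`.
#'
#' @param sim a [pearson_similarity()] result.
#' @param absolute if `TRUE`, operate on `|r|` instead of signed r.
#' @return the threshold, a scalar.
#' @export
max_no_isolate_threshold <- function(sim, absolute = FALSE) {
  stopifnot(inherits(sim, "similarity_matrix"))
  r <- sim$r
  if (absolute) r <- abs(r)
  n <- nrow(r)
  if (n < 2L) stop("need at least 2 genes")
  diag(r) <- -Inf
  min(apply(r, 1L, max))
}

#' Prune the complete similarity graph at a threshold
#'
#' Keeps the edge (i, j), i != j, iff `r[i, j] >= t`; the edge weight is the
#' correlation itself. Retained edges must have positive weight because the
#' aggregation step normalizes edge weights to a convex combination; choose a
#' positive threshold (or `absolute = TRUE`) if negative correlations
#' survive.
#'
#' @param sim a [pearson_similarity()] result.
#' @param t threshold in `[-1, 1]`.
#' @param absolute if `TRUE`, threshold and weight by `|r|`.
#' @return a [gene_graph()] over all genes of `sim`.
#' @export
prune_graph <- function(sim, t, absolute = FALSE) {
  stopifnot(inherits(sim, "similarity_matrix"), t >= -1, t <= 1)
  r <- sim$r
  if (absolute) r <- abs(r)
  n <- nrow(r)
  keep <- which(upper.tri(r) & r >= t, arr.ind = TRUE)
  w <- r[keep]
  if (any(w <= 0))
    stop("pruning retained non-positive edge weights; raise the threshold or use absolute = TRUE")
  edges <- if (nrow(keep)) {
    data.frame(from = sim$gene_ids[keep[, 1L]],
               to = sim$gene_ids[keep[, 2L]],
               weight = w, stringsAsFactors = FALSE)
  } else NULL
  gene_graph(edges, nodes = sim$gene_ids)
}

#' Merge the co-expression graph with the prior interaction graph
#'
#' The merged edge set is the union of the two edge sets. An edge present in
#' both graphs gets the mean of the two weights; an edge present in only one
#' graph gets half its weight. The node set is the union of the node sets.
#'
#' @param gp co-expression [gene_graph()].
#' @param gs prior [gene_graph()], already filtered to the same universe.
#' @return the merged [gene_graph()].
#' @export
merge_graphs <- function(gp, gs) {
  stopifnot(inherits(gp, "gene_graph"), inherits(gs, "gene_graph"))
  kp <- paste(gp$edges$from, gp$edges$to, sep = "\r")
  ks <- paste(gs$edges$from, gs$edges$to, sep = "\r")
  wp <- setNames(gp$edges$weight, kp)
  ws <- setNames(gs$edges$weight, ks)
  keys <- union(kp, ks)
  w <- (unname(ifelse(keys %in% kp, wp[keys], 0)) +
        unname(ifelse(keys %in% ks, ws[keys], 0))) / 2
  edges <- if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    data.frame(from = parts[, 1L], to = parts[, 2L], weight = w,
               stringsAsFactors = FALSE)
  } else NULL
  gene_graph(edges, nodes = union(gp$nodes, gs$nodes))
}

#' Build the merged gene graph from expression and a prior graph
#'
#' Convenience wrapper: Pearson similarity, threshold selection (`"auto"` =
#' [max_no_isolate_threshold()]), pruning, and merging with the prior.
#'
#' @param em an [expression_matrix()].
#' @param prior a prior [gene_graph()] over the same genes, or `NULL` for
#'   none (the pruned graph is then merged with an empty prior, halving all
#'   weights).
#' @param threshold `"auto"` or a numeric threshold.
#' @param absolute threshold on absolute correlation.
#' @return list with `graph` (merged [gene_graph()]), `threshold`, and edge
#'   counts `n_expr_edges`, `n_prior_edges`, `n_merged_edges`.
#' @export
build_gene_graph <- function(em, prior = NULL, threshold = "auto",
                             absolute = FALSE) {
  sim <- pearson_similarity(em)
  t <- if (identical(threshold, "auto")) {
    max_no_isolate_threshold(sim, absolute = absolute)
  } else {
    as.numeric(threshold)
  }
  gp <- prune_graph(sim, t, absolute = absolute)
  if (is.null(prior)) prior <- gene_graph(NULL, nodes = gp$nodes)
  merged <- merge_graphs(gp, prior)
  list(graph = merged, threshold = t,
       n_expr_edges = n_edges(gp),
       n_prior_edges = n_edges(prior),
       n_merged_edges = n_edges(merged))
}
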