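#' Construct a weighted gene graph
#'
#' Undirected weighted graph over gene identifiers. Edges are canonicalized
#' so that `from < to` lexicographically; self loops are forbidden, every
#' weight must be strictly positive, and each unordered pair occurs at most
#' once.
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (zero rows
#'   allowed).
#' @param nodes character vector of node ids; defaults to the edge endpoints.
#' @return an object of class `gene_graph` with elements `nodes` and `edges`.
#' @export
gene_graph <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("from", "to", "weight") %in% names(edges)))
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
      stop("edge weights must be strictly positive and finite")
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges after canonicalization")
    edges <- edges[order(edges$from, edges$to, method = "radix"), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  if (nrow(edges) && !all(c(edges$from, edges$to) %in% nodes))
    stop("edge endpoint outside the node set")
  structure(list(nodes = nodes, edges = edges), class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("Gene graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_edges <- function(g) nrow(g$edges)

#' Load a prior interaction edge list
#'
#' Reads a TSV with columns `fromNode`, `toNode`, `weight` (case-insensitive;
#' `from`/`to`/`score` dialects are mapped). Edges with either endpoint
#' outside `universe` are dropped, weights are divided by `score_divisor`
#' (use 1000 for STRING-style 0-1000 combined scores), unordered duplicate
#' pairs keep the maximum weight and non-positive weights are removed.
#'
#' @param path file path.
#' @param universe character vector of gene ids under investigation.
#' @param score_divisor positive divisor applied to raw weights (default 1).
#' @return a [gene_graph()] over `universe`.
#' @export
load_edge_list <- function(path, universe, score_divisor = 1) {
  stopifnot(score_divisor > 0)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  fcol <- match(TRUE, nm %in% c("fromnode", "from", "node1", "gene1"))
  tcol <- match(TRUE, nm %in% c("tonode", "to", "node2", "gene2"))
  wcol <- match(TRUE, nm %in% c("weight", "score", "combined_score"))
  if (anyNA(c(fcol, tcol, wcol)))
    stop("edge list must have fromNode/toNode/weight columns")
  from <- as.character(df[[fcol]])
  to <- as.character(df[[tcol]])
  w <- as.numeric(df[[wcol]]) / score_divisor
  keep <- from %in% universe & to %in% universe & from != to & w > 0
  from <- from[keep]; to <- to[keep]; w <- w[keep]
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  if (length(w)) {
    key <- paste(from, to, sep = "\r")
    mx <- tapply(w, key, max)
    parts <- do.call(rbind, strsplit(names(mx), "\r", fixed = TRUE))
    edges <- data.frame(from = parts[, 1L], to = parts[, 2L],
                        weight = as.numeric(mx), stringsAsFactors = FALSE)
  } else {
    edges <- NULL
    warning("no prior edges remain after universe filtering")
  }
  gene_graph(edges, nodes = universe)
}

#' Write a gene graph as a fromNode/toNode/weight TSV
#'
#' @param g a [gene_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  df <- data.frame(fromNode = g$edges$from, toNode = g$edges$to,
                   weight = g$edges$weight, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

## Sparse symmetric adjacency; weighted or 0/1 indicator.
graph_adjacency <- function(g, indicator = FALSE) {
  n <- length(g$nodes)
  i <- match(g$edges$from, g$nodes)
  j <- match(g$edges$to, g$nodes)
  x <- if (indicator) rep(1, length(i)) else g$edges$weight
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(x, x),
                            dims = c(n, n),
                            dimnames = list(g$nodes, g$nodes))
  A
}

## Neighbor adjacency list: for each node, data.frame-free list with
## integer neighbor indices and edge weights.
graph_neighbors <- function(g) {
  n <- length(g$nodes)
  i <- match(g$edges$from, g$nodes)
  j <- match(g$edges$to, g$nodes)
  nb <- vector("list", n)
  wt <- vector("list", n)
  all_src <- c(i, j)
  all_dst <- c(j, i)
  all_w <- rep(g$edges$weight, 2L)
  o <- order(all_src)
  all_src <- all_src[o]; all_dst <- all_dst[o]; all_w <- all_w[o]
  idx <- split(seq_along(all_src), all_src)
  for (k in seq_len(n)) {
    nb[[k]] <- integer(0)
    wt[[k]] <- numeric(0)
  }
  for (nm in names(idx)) {
    k <- as.integer(nm)
    nb[[k]] <- all_dst[idx[[nm]]]
    wt[[k]] <- all_w[idx[[nm]]]
  }
  list(neighbors = nb, weights = wt, nodes = g$nodes)
}
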