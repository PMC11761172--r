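#' Number of modules by a dynamic hybrid tree cut
#'
#' Builds the average-linkage dendrogram of the correlation distance
#' `1 - cor` between the rows of `X` and counts the branches that qualify as
#' modules under a dynamic (height-adaptive) cut: scanning the merges bottom
#' up, two branches joined at height h are both declared modules when each
#' has at least `min_module_size` members, a core scatter (mean internal
#' merge height) below the deep-split-dependent ceiling, and a separation
#' gap `h - top` above the deep-split-dependent floor. Rows the cut leaves
#' unlabeled are attached to the nearest module centroid before counting, so
#' every row is assigned. If no merge qualifies the result is a single
#' module.
#'
#' @param X numeric matrix, rows = genes (no zero-variance rows).
#' @param min_module_size minimum genes per module (default 30).
#' @param deep_split split sensitivity 0-4 (default 2); higher splits more.
#' @return the module count `k` (>= 1). With fewer than
#'   `2 * min_module_size` rows no split can satisfy the size floor and 1 is
#'   returned with a warning.
#' @export
dht_module_count <- function(X, min_module_size = 30L, deep_split = 2L) {
  lab <- dht_labels(X, min_module_size, deep_split)
  max(1L, max(lab))
}

## Full dynamic-cut labelling; 0 = unassigned (later attached to nearest
## module centroid). Internal to dht_module_count()/hcm() but shared.
dht_labels <- function(X, min_module_size = 30L, deep_split = 2L) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  n <- nrow(X)
  if (n < 2L * min_module_size) {
    warning(sprintf(
      "%d rows cannot be split under a minimum module size of %d; one module",
      n, min_module_size))
    return(rep(1L, n))
  }
  # rows with zero variance have no defined correlation distance; they are
  # held out of the tree and attached to the nearest centroid afterwards
  v <- apply(X, 1L, var)
  zv <- v == 0
  if (sum(!zv) < 2L) return(rep(1L, n))
  Xa <- X[!zv, , drop = FALSE]
  d <- 1 - cor(t(Xa))
  ht <- hclust(as.dist(d), method = "average")
  n_act <- nrow(Xa)
  h <- ht$height
  if (max(h) <= 0) return(rep(1L, n))  # all rows identical
  cut_height <- 0.99 * max(h)
  ref_height <- as.numeric(quantile(h, 0.05))
  # deep-split 0..4 mapped to a core-scatter ceiling and separation-gap floor
  # on the (ref, cut) height range
  core_frac <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1L]
  gap_frac <- (1 - core_frac) * 3 / 4
  max_core <- ref_height + core_frac * (cut_height - ref_height)
  min_gap <- gap_frac * (cut_height - ref_height)

  # bottom-up scan over merges: each active branch tracks its size, the
  # height of its last substantial internal merge (joins where the smaller
  # side is below `small_cut` are stragglers accreting onto the branch and
  # do not reset its top), the mean internal merge height (core scatter)
  # and whether it already contains finalized modules
  small_cut <- max(2L, ceiling(min_module_size / 3))
  branch <- vector("list", n_act - 1L)
  labels_act <- rep(0L, n_act)
  next_label <- 0L
  side_info <- function(idx) {
    if (idx < 0) {
      list(members = -idx, size = 1L, top = 0, hsum = 0, hcnt = 0L,
           finalized = FALSE)
    } else {
      branch[[idx]]
    }
  }
  qualifies <- function(b, h_i) {
    core <- if (b$hcnt > 0L) b$hsum / b$hcnt else 0
    b$size >= min_module_size && core <= max_core && (h_i - b$top) >= min_gap
  }
  for (i in seq_len(n_act - 1L)) {
    L <- side_info(ht$merge[i, 1L])
    R <- side_info(ht$merge[i, 2L])
    ql <- qualifies(L, h[i])
    qr <- qualifies(R, h[i])
    # a side is "settled" if it already holds modules; a settled side lets
    # the other side split off on its own merit
    if ((ql || L$finalized) && (qr || R$finalized)) {
      if (!L$finalized && ql) {
        next_label <- next_label + 1L
        labels_act[L$members] <- next_label
        L$finalized <- TRUE
      }
      if (!R$finalized && qr) {
        next_label <- next_label + 1L
        labels_act[R$members] <- next_label
        R$finalized <- TRUE
      }
    }
    substantial <- min(L$size, R$size) >= small_cut
    branch[[i]] <- list(
      members = c(L$members, R$members),
      size = L$size + R$size,
      top = if (substantial) h[i] else max(L$top, R$top),
      hsum = L$hsum + R$hsum + h[i],
      hcnt = L$hcnt + R$hcnt + 1L,
      finalized = L$finalized || R$finalized)
  }
  if (next_label == 0L) return(rep(1L, n))
  labels <- rep(0L, n)
  labels[!zv] <- labels_act
  # attach unassigned rows (cut leftovers and zero-variance rows) to the
  # nearest module centroid
  if (any(labels == 0L)) {
    cent <- do.call(rbind, lapply(seq_len(next_label), function(m)
      colMeans(X[labels == m, , drop = FALSE])))
    for (i in which(labels == 0L)) {
      dd <- rowSums(sweep(cent, 2L, X[i, ])^2)
      labels[i] <- which.min(dd)
    }
  }
  labels
}

#' Module partition container
#'
#' @param gene_ids character gene ids.
#' @param module integer module id per gene, values in `1..k`, every module
#'   non-empty.
#' @return object of class `module_partition` with `gene_ids`, `module_of`
#'   (named integer vector) and `k`.
#' @export
module_partition <- function(gene_ids, module) {
  module <- as.integer(module)
  stopifnot(length(gene_ids) == length(module), all(module >= 1L))
  k <- max(module)
  if (!all(seq_len(k) %in% module)) stop("empty module id in 1..k")
  structure(list(gene_ids = as.character(gene_ids),
                 module_of = setNames(module, gene_ids), k = k),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- table(x$module_of)
  cat(sprintf("Module partition: %d genes in %d modules (sizes %s)\n",
              length(x$gene_ids), x$k, paste(tab, collapse = ", ")))
  invisible(x)
}

#' Assign genes to k modules by Lloyd's k-means
#'
#' Centroids are initialized as a seeded uniform sample of k distinct rows;
#' iterations stop when assignments no longer change (or at `max_iter`).
#' A cluster that empties is re-seeded from the point farthest from its
#' centroid.
#'
#' @param X numeric matrix, rows = genes (with rownames).
#' @param k number of modules, `1 <= k <= nrow(X)`.
#' @param seed integer seed (initialization only; the iterations are
#'   deterministic).
#' @param max_iter iteration cap (default 300).
#' @param n_start number of seeded random restarts; the assignment with the
#'   lowest within-cluster sum of squares wins (default 10 — a single
#'   uniform draw of centroids is easily trapped in a poor local optimum).
#' @return a [module_partition()] with attributes `wss` (final objective)
#'   and `wss_trace` (per-iteration objective of the winning restart).
#' @export
kmeans_assign <- function(X, k, seed = 1L, max_iter = 300L, n_start = 10L) {
  stopifnot(is.matrix(X), k >= 1L)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of genes")
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(n))
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(n_start)) {
    cent <- X[sample.int(n, k), , drop = FALSE]
    assign_prev <- rep(0L, n)
    wss_trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(cent) +
        outer(rep(1, n), rowSums(cent^2))
      assign <- max.col(-d2, ties.method = "first")
      for (m in seq_len(k)) {
        if (!any(assign == m)) {
          far <- which.max(d2[cbind(seq_len(n), assign)])
          assign[far] <- m
        }
      }
      if (identical(assign, assign_prev)) break
      assign_prev <- assign
      cent <- do.call(rbind, lapply(seq_len(k), function(m)
        colMeans(X[assign == m, , drop = FALSE])))
      wss_trace <- c(wss_trace, sum(vapply(seq_len(n), function(i)
        sum((X[i, ] - cent[assign[i], ])^2), numeric(1L))))
    }
    wss <- sum(vapply(seq_len(n), function(i)
      sum((X[i, ] - cent[assign[i], ])^2), numeric(1L)))
    if (is.null(best) || wss < best$wss)
      best <- list(assign = assign, wss = wss, wss_trace = wss_trace)
  }
  out <- module_partition(rownames(X), best$assign)
  attr(out, "wss") <- best$wss
  attr(out, "wss_trace") <- best$wss_trace
  out
}

#' Hybrid clustering: dynamic tree cut chooses k, k-means assigns
#'
#' @param Z embedding matrix (genes x d with rownames), or a
#'   [train_embeddings()] result.
#' @param min_module_size minimum genes per module for the tree cut.
#' @param seed seed passed to [kmeans_assign()].
#' @param deep_split tree-cut sensitivity 0-4.
#' @return a [module_partition()].
#' @export
hcm <- function(Z, min_module_size = 30L, seed = 1L, deep_split = 2L) {
  if (inherits(Z, "gene_embedding")) Z <- Z$Z
  stopifnot(is.matrix(Z))
  if (all(apply(Z, 1L, var) == 0) ||
      all(abs(sweep(Z, 2L, Z[1L, ])) < 1e-12)) {
    return(module_partition(rownames(Z) %||% paste0("g", seq_len(nrow(Z))),
                            rep(1L, nrow(Z))))
  }
  k <- dht_module_count(Z, min_module_size = min_module_size,
                        deep_split = deep_split)
  if (k == 1L) {
    return(module_partition(rownames(Z) %||% paste0("g", seq_len(nrow(Z))),
                            rep(1L, nrow(Z))))
  }
  kmeans_assign(Z, k, seed = seed)
}

#' Internal clustering validity indices
#'
#' Silhouette index (mean over points of `(b - a) / max(a, b)`, singletons
#' scoring 0), Calinski-Harabasz index (between / within variance ratio
#' scaled by `(n - k) / (k - 1)`) and Davies-Bouldin index (mean over
#' clusters of the worst `(s_i + s_j) / d(c_i, c_j)`), all on Euclidean
#' distance.
#'
#' @param X numeric matrix of the clustered points (rows).
#' @param p a [module_partition()] over the rows of `X` (k >= 2).
#' @return list with `SI`, `CHI`, `DBI`.
#' @export
clustering_indices <- function(X, p) {
  stopifnot(is.matrix(X), inherits(p, "module_partition"))
  lab <- as.integer(p$module_of)
  n <- nrow(X)
  stopifnot(length(lab) == n)
  k <- p$k
  if (k < 2L) stop("validity indices are undefined for k = 1")
  D <- as.matrix(dist(X))
  sizes <- tabulate(lab, k)

  # silhouette
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- lab[i]
    if (sizes[own] == 1L) { sil[i] <- 0; next }
    a <- sum(D[i, lab == own]) / (sizes[own] - 1L)
    b <- min(vapply(setdiff(seq_len(k), own), function(m)
      mean(D[i, lab == m]), numeric(1L)))
    sil[i] <- (b - a) / max(a, b)
  }
  SI <- mean(sil)

  cent <- do.call(rbind, lapply(seq_len(k), function(m)
    colMeans(X[lab == m, , drop = FALSE])))
  grand <- colMeans(X)
  ssb <- sum(sizes * rowSums(sweep(cent, 2L, grand)^2))
  ssw <- sum(vapply(seq_len(n), function(i)
    sum((X[i, ] - cent[lab[i], ])^2), numeric(1L)))
  CHI <- if (ssw == 0) Inf else (ssb / (k - 1L)) / (ssw / (n - k))

  s <- vapply(seq_len(k), function(m)
    mean(sqrt(rowSums(sweep(X[lab == m, , drop = FALSE], 2L,
                            cent[m, ])^2))), numeric(1L))
  DBI <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      dc <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      (s[i] + s[j]) / dc
    }, numeric(1L)))
  }, numeric(1L)))

  list(SI = SI, CHI = CHI, DBI = DBI)
}

#' Compare the hybrid clustering against standard baselines
#'
#' Runs k-means, average-linkage hierarchical clustering, a spectral
#' embedding of the Pearson similarity followed by k-means, and fuzzy
#' c-means, all at the same k as the hybrid partition, and reports the three
#' validity indices for each.
#'
#' @param X matrix the partitions are evaluated on (typically the embedding
#'   matrix).
#' @param p the hybrid [module_partition()] (provides k).
#' @param seed seed for the seeded baselines.
#' @return data.frame with method, SI, CHI, DBI.
#' @export
module_benchmark <- function(X, p, seed = 1L) {
  k <- p$k
  stopifnot(k >= 2L)
  ids <- rownames(X) %||% paste0("g", seq_len(nrow(X)))
  rownames(X) <- ids
  res <- list(hcm = p)
  set.seed(stage_seed(seed, "benchmark-kmeans"))
  res$kmeans <- module_partition(ids, kmeans(X, k, nstart = 5L)$cluster)
  hc <- hclust(as.dist(1 - cor(t(X))), method = "average")
  res$hierarchical <- module_partition(ids, cutree(hc, k))
  # spectral: top-k eigenvectors of the normalized similarity, then k-means
  Sims <- (cor(t(X)) + 1) / 2
  dd <- 1 / sqrt(pmax(rowSums(Sims), 1e-12))
  Lsym <- sweep(sweep(Sims, 1L, dd, "*"), 2L, dd, "*")
  ev <- eigen(Lsym, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  ev <- ev / pmax(sqrt(rowSums(ev^2)), 1e-12)
  set.seed(stage_seed(seed, "benchmark-spectral"))
  res$spectral <- module_partition(ids, kmeans(ev, k, nstart = 5L)$cluster)
  set.seed(stage_seed(seed, "benchmark-fcm"))
  fc <- e1071::cmeans(X, centers = k, m = 2)
  res$fcm <- module_partition(ids, fc$cluster)
  out <- do.call(rbind, lapply(names(res), function(nm) {
    ix <- clustering_indices(X, res[[nm]])
    data.frame(method = nm, SI = ix$SI, CHI = ix$CHI, DBI = ix$DBI,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
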