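#' Names of the ten per-module feature evaluators
#'
#' @return character vector of evaluator names accepted by [rank_genes()].
#' @export
evaluator_names <- function() {
  c("MIFS", "MIC", "ANOVA", "ReliefF", "GBDT", "RF",
    "Lasso", "Ridge", "LR", "DT")
}

## Two-group F statistic per column (equal to the square of the pooled t).
anova_f <- function(X, y) {
  y <- as.integer(factor(y)) - 1L
  n1 <- sum(y == 0L); n2 <- sum(y == 1L)
  n <- n1 + n2
  m1 <- colMeans(X[y == 0L, , drop = FALSE])
  m2 <- colMeans(X[y == 1L, , drop = FALSE])
  grand <- colMeans(X)
  ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ssw <- colSums(sweep(X[y == 0L, , drop = FALSE], 2L, m1)^2) +
         colSums(sweep(X[y == 1L, , drop = FALSE], 2L, m2)^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[is.nan(f)] <- 0  # 0/0: constant gene; Inf (perfect separator) is kept
  f
}

## ReliefF weights: contrast of distances to k nearest hits and misses,
## range-normalized differences, all samples used as anchors.
relieff_weights <- function(X, y, k = 5L) {
  n <- nrow(X); p <- ncol(X)
  y <- factor(y)
  rng <- apply(X, 2L, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  Xn <- sweep(X, 2L, rng, "/")
  D <- as.matrix(dist(Xn, method = "manhattan"))
  prior <- table(y) / n
  w <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- setdiff(same, i)
    if (length(same) == 0L) next
    kh <- min(k, length(same))
    hits <- same[order(D[i, same])[seq_len(kh)]]
    dh <- colMeans(abs(sweep(Xn[hits, , drop = FALSE], 2L, Xn[i, ])))
    for (cl in levels(y)[levels(y) != y[i]]) {
      other <- which(y == cl)
      km <- min(k, length(other))
      miss <- other[order(D[i, other])[seq_len(km)]]
      dm <- colMeans(abs(sweep(Xn[miss, , drop = FALSE], 2L, Xn[i, ])))
      coef <- prior[[cl]] / (1 - prior[[as.character(y[i])]])
      w <- w + coef * dm / n
    }
    w <- w - dh / n
  }
  w
}

## Binned maximal-information-style score: best normalized mutual information
## over equal-frequency binnings of x, grid budget B = n^0.6 (y is binary, so
## the normalizer is log 2).
mic_score <- function(x, y, seed = 1L) {
  n <- length(x)
  kmax <- max(2L, floor(max(4, n^0.6) / 2))
  best <- 0
  for (kx in 2L:max(2L, kmax)) {
    mi <- mutual_information(x, y, n_bins = kx, seed = seed)
    best <- max(best, mi / log(2))
  }
  best
}

## Minimum-norm least-squares coefficients (centered), via SVD.
minnorm_coef <- function(X, y) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d[1], 1e-12) * 1e-10
  if (!any(pos)) return(numeric(ncol(X)))
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos]))
}

#' Score and rank the genes of one module with a single evaluator
#'
#' Supported evaluators: `MIFS` (discretized mutual information with the
#' label), `MIC` (binned mutual-information grid score), `ANOVA` (two-group
#' F statistic), `ReliefF` (nearest hit/miss feature weights), `GBDT`
#' (gradient-boosted trees, depth 3, 100 rounds), `RF` (random forest,
#' depth 3, 100 trees, impurity importance), `Lasso` (L1 regression,
#' lambda 0.01, absolute coefficients), `Ridge` (L2 regression, lambda 1,
#' absolute coefficients), `LR` (minimum-norm linear regression, absolute
#' coefficients) and `DT` (single decision tree importance). Scores are
#' sorted descending with ties broken by ascending gene id, so every ranking
#' is deterministic given the seed.
#'
#' @param evaluator one of [evaluator_names()].
#' @param X numeric matrix, samples x genes, with gene colnames.
#' @param y binary labels (length `nrow(X)`, both classes with >= 2
#'   samples).
#' @param seed integer seed for the stochastic evaluators.
#' @return object of class `ranked_list`: list with `evaluator`, `gene_ids`
#'   (best first) and `scores` (same order).
#' @export
rank_genes <- function(evaluator, X, y, seed = 1L) {
  evaluator <- match.arg(evaluator, evaluator_names())
  stopifnot(is.matrix(X), ncol(X) >= 1L)
  if (is.null(colnames(X))) stop("X needs gene colnames")
  yf <- binary_factor(y)
  if (nlevels(yf) != 2L) stop("labels must contain exactly 2 classes")
  if (any(table(yf) < 2L)) stop("each class needs at least 2 samples")
  y01 <- as.integer(yf) - 1L
  p <- ncol(X)
  ids <- colnames(X)
  seed <- stage_seed(seed, paste0("rank-", evaluator))
  scores <- switch(
    evaluator,
    MIFS = vapply(seq_len(p), function(j)
      mutual_information(X[, j], y01, seed = seed + j), numeric(1L)),
    MIC = vapply(seq_len(p), function(j)
      mic_score(X[, j], y01, seed = seed + j), numeric(1L)),
    ANOVA = anova_f(X, y01),
    ReliefF = relieff_weights(X, yf),
    GBDT = {
      set.seed(seed)
      bst <- xgboost::xgboost(
        x = X, y = yf, max_depth = 3, nrounds = 100,
        learning_rate = 0.3, nthreads = 1, verbosity = 0)
      imp <- xgboost::xgb.importance(model = bst)
      s <- setNames(rep(0, p), ids)
      s[imp$Feature] <- imp$Gain
      unname(s)
    },
    RF = {
      fit <- ranger::ranger(
        x = X, y = yf, num.trees = 100, max.depth = 3,
        importance = "impurity", seed = seed, num.threads = 1)
      unname(fit$variable.importance[ids])
    },
    Lasso = penalized_scores(X, y01, alpha = 1, lambda = 0.01),
    Ridge = penalized_scores(X, y01, alpha = 0, lambda = 1),
    LR = abs(minnorm_coef(X, y01)),
    DT = {
      set.seed(seed)
      df <- data.frame(X, check.names = FALSE)
      df$.y <- yf
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = 3, cp = 0, minsplit = 4,
                            xval = 0))
      s <- setNames(rep(0, p), ids)
      vi <- fit$variable.importance
      if (!is.null(vi)) s[names(vi)] <- vi
      unname(s)
    })
  scores <- unname(scores)
  scores[is.na(scores)] <- 0
  o <- order_scores(scores, ids)
  structure(list(evaluator = evaluator, gene_ids = ids[o],
                 scores = scores[o]),
            class = "ranked_list")
}

## |coefficients| from a single-lambda elastic-net fit; falls back to
## absolute correlation when the module has a single gene (glmnet needs two).
penalized_scores <- function(X, y01, alpha, lambda) {
  if (ncol(X) < 2L)
    return(abs(cor(X[, 1L], y01)))
  fit <- glmnet::glmnet(X, y01, family = "gaussian", alpha = alpha,
                        lambda = lambda, standardize = TRUE)
  abs(as.numeric(fit$beta))
}

#' Fuse ranked lists with robust rank aggregation
#'
#' For each gene the normalized rank vector across the m lists is sorted
#' ascending and scored by `rho = min_k P(Beta(k, m - k + 1) <= r_(k))`, the
#' smallest order-statistic tail probability: how surprisingly often the
#' gene ranks near the top under the null of random, independent rankings.
#' Genes are ordered by ascending rho, ties broken by ascending gene id.
#'
#' @param lists list of [rank_genes()] results (or plain character rankings)
#'   that are permutations of one common gene set.
#' @param bonferroni if `TRUE`, multiply rho by m (the published correction);
#'   default `FALSE` — the ordering is unaffected for fixed m.
#' @return data.frame with `gene_id` (best first) and `rho`.
#' @export
rra_aggregate <- function(lists, bonferroni = FALSE) {
  stopifnot(length(lists) >= 1L)
  rankings <- lapply(lists, function(l) {
    if (inherits(l, "ranked_list")) l$gene_ids else as.character(l)
  })
  genes <- sort(rankings[[1L]])
  for (r in rankings) {
    if (!identical(sort(r), genes))
      stop("all lists must be permutations of the same gene set")
  }
  n <- length(genes)
  m <- length(rankings)
  R <- vapply(rankings, function(r) match(genes, r) / n, numeric(n))
  R <- matrix(R, nrow = n)
  rho <- apply(R, 1L, function(r) {
    r <- sort(r)
    min(pbeta(r, seq_len(m), m - seq_len(m) + 1))
  })
  if (bonferroni) rho <- pmin(1, rho * m)
  o <- order(rho, genes, method = "radix")
  data.frame(gene_id = genes[o], rho = rho[o], stringsAsFactors = FALSE)
}

#' Select per-module candidate genes by ensemble ranking
#'
#' Within each module, all ten evaluators rank the module's genes, the
#' rankings are fused with [rra_aggregate()], and the best
#' `min(top_n, module size)` genes are kept. The pooled candidate set is
#' their union (modules are disjoint, so there are no duplicates).
#'
#' @param p a [module_partition()].
#' @param em an [expression_matrix()] covering the partition's genes.
#' @param y binary labels (defaults to `em$labels`).
#' @param top_n candidates kept per module (default 10).
#' @param seed pipeline seed, fanned out per module and evaluator.
#' @return object of class `candidate_set`: list with `per_module` (one
#'   fused ranking data.frame per module) and `pooled` (character).
#' @export
select_candidates <- function(p, em, y = NULL, top_n = 10L, seed = 1L) {
  stopifnot(inherits(p, "module_partition"), inherits(em, "expr_matrix"))
  y <- y %||% em$labels
  if (is.null(y)) stop("labels are required for feature selection")
  per_module <- vector("list", p$k)
  top <- vector("list", p$k)
  for (m in seq_len(p$k)) {
    genes <- p$gene_ids[p$module_of == m]
    Xm <- t(em$values[genes, , drop = FALSE])
    lists <- lapply(evaluator_names(), function(ev)
      rank_genes(ev, Xm, y, seed = stage_seed(seed, paste0("module-", m))))
    fused <- rra_aggregate(lists)
    per_module[[m]] <- fused
    top[[m]] <- head(fused$gene_id, min(top_n, length(genes)))
  }
  structure(list(per_module = per_module, pooled = unlist(top),
                 top_n = top_n),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set: %d genes pooled from %d modules\n",
              length(x$pooled), length(x$per_module)))
  invisible(x)
}

#' Refine pooled candidates to the final biomarker panel
#'
#' Re-ranks the pooled candidates by discretized mutual information between
#' each gene's expression and the group label (a seeded, parameter-free
#' estimator) and keeps the top `panel_size` genes.
#'
#' @param candidates a [select_candidates()] result (or a character vector
#'   of gene ids).
#' @param em an [expression_matrix()].
#' @param y binary labels (defaults to `em$labels`).
#' @param panel_size final panel size (default 10).
#' @param seed integer seed for the MI estimator.
#' @return data.frame with `gene_id` and `mi` (nats), best first, of class
#'   `biomarker_panel`.
#' @export
mifs_refine <- function(candidates, em, y = NULL, panel_size = 10L,
                        seed = 1L) {
  pooled <- if (inherits(candidates, "candidate_set")) candidates$pooled
            else as.character(candidates)
  stopifnot(inherits(em, "expr_matrix"), all(pooled %in% em$gene_ids))
  if (length(pooled) < panel_size)
    stop("panel_size exceeds the pooled candidate count")
  y <- y %||% em$labels
  if (is.null(y)) stop("labels are required")
  y01 <- as.integer(binary_factor(y)) - 1L
  s <- stage_seed(seed, "mifs-refine")
  mi <- vapply(seq_along(pooled), function(i)
    mutual_information(em$values[pooled[i], ], y01, seed = s + i),
    numeric(1L))
  o <- order(-mi, pooled, method = "radix")
  out <- data.frame(gene_id = pooled[o][seq_len(panel_size)],
                    mi = mi[o][seq_len(panel_size)],
                    stringsAsFactors = FALSE)
  class(out) <- c("biomarker_panel", class(out))
  out
}
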