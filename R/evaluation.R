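#' Per-gene differential tests for a panel
#'
#' Two-sided Welch t-test and two-sided Wilcoxon rank-sum test for each
#' panel gene between the two groups, with no multiplicity correction (an
#' optional FDR column is appended for convenience). Genes with zero
#' variance in both groups have an undefined t statistic; their p-values are
#' reported as 1 with `degenerate = TRUE`.
#'
#' @param em an [expression_matrix()].
#' @param y binary labels (defaults to `em$labels`).
#' @param panel character vector of gene ids present in `em`.
#' @return data.frame with `gene_id`, `p_t`, `p_w`, `fdr_t`, `fdr_w`,
#'   `degenerate`.
#' @export
per_gene_tests <- function(em, y = NULL, panel = em$gene_ids) {
  stopifnot(inherits(em, "expr_matrix"), all(panel %in% em$gene_ids))
  y <- binary_factor(y %||% em$labels)
  stopifnot(nlevels(y) == 2L, all(table(y) >= 2L))
  g1 <- y == levels(y)[1L]
  res <- lapply(panel, function(g) {
    a <- em$values[g, g1]
    b <- em$values[g, !g1]
    if (var(a) == 0 && var(b) == 0) {
      data.frame(gene_id = g, p_t = 1, p_w = 1, degenerate = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      pt <- t.test(a, b, var.equal = FALSE)$p.value
      pw <- suppressWarnings(wilcox.test(a, b, exact = NULL)$p.value)
      data.frame(gene_id = g, p_t = pt, p_w = pw, degenerate = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$fdr_t <- p.adjust(out$p_t, "BH")
  out$fdr_w <- p.adjust(out$p_w, "BH")
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the thresholds defined by the unique scores; at each threshold the
#' confusion counts give one (FPR, TPR) point (`TPR = TP / (TP + FN)`,
#' `FPR = FP / (FP + TN)`), and the AUC is the trapezoidal area under the
#' resulting curve. With ties this equals the Mann-Whitney statistic with
#' ties counted one half.
#'
#' @param scores numeric per-sample scores, larger = more case-like.
#' @param y binary labels; the second factor level (or the larger of two
#'   numeric values) is the positive class.
#' @return list with `auc` and `roc` (data.frame `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)).
#' @export
roc_auc <- function(scores, y) {
  y <- binary_factor(y)
  if (nlevels(y) != 2L) stop("need both classes present")
  pos <- y == levels(y)[2L]
  P <- sum(pos); N <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / P, numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / N, numeric(1L))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(auc = auc, roc = roc)
}

#' Leave-one-out decision-tree classification of a panel
#'
#' For each sample a depth-limited classification tree is trained on the
#' remaining samples restricted to the panel genes, and the held-out sample
#' is scored with the positive-class leaf probability. All held-out scores
#' are pooled into a single ROC (the only way leave-one-out yields a
#' curve).
#'
#' @param em an [expression_matrix()].
#' @param y binary labels (defaults to `em$labels`).
#' @param panel character vector of panel gene ids.
#' @param seed integer seed (tree fitting is deterministic; the seed fixes
#'   surrogate tie-breaks).
#' @param max_depth tree depth cap (default 3).
#' @return list with `scores` (named per-sample), `auc`, `roc`.
#' @export
loocv_classify <- function(em, y = NULL, panel, seed = 1L, max_depth = 3L) {
  stopifnot(inherits(em, "expr_matrix"), all(panel %in% em$gene_ids))
  y <- binary_factor(y %||% em$labels)
  n <- ncol(em$values)
  stopifnot(nlevels(y) == 2L, n >= 3L)
  X <- t(em$values[panel, , drop = FALSE])
  colnames(X) <- panel
  pos_level <- levels(y)[2L]
  scores <- numeric(n)
  set.seed(as.integer(seed))
  for (i in seq_len(n)) {
    df <- data.frame(X[-i, , drop = FALSE], check.names = FALSE)
    df$.y <- y[-i]
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = max_depth, cp = 0, minsplit = 4,
                          xval = 0))
    newd <- data.frame(X[i, , drop = FALSE], check.names = FALSE)
    scores[i] <- predict(fit, newdata = newd, type = "prob")[, pos_level]
  }
  names(scores) <- em$sample_ids
  r <- roc_auc(scores, y)
  list(scores = scores, auc = r$auc, roc = r$roc)
}

#' Validate a biomarker panel on an external cohort
#'
#' Panel genes absent from the external matrix are reported and dropped.
#' The remaining genes get per-gene rank-sum (and t) tests and individual
#' AUCs; the panel as a whole is scored by leave-one-out decision-tree
#' classification on the external cohort.
#'
#' @param em_ext external [expression_matrix()].
#' @param y_ext external binary labels (defaults to `em_ext$labels`).
#' @param panel character vector of panel gene ids.
#' @param seed integer seed.
#' @return object of class `biomarker_report`: list with `panel`,
#'   `dropped`, `tests` (per-gene p-values), `gene_auc`, `panel_auc`,
#'   `roc`.
#' @export
external_validate <- function(em_ext, y_ext = NULL, panel, seed = 1L) {
  stopifnot(inherits(em_ext, "expr_matrix"))
  y <- binary_factor(y_ext %||% em_ext$labels)
  present <- panel[panel %in% em_ext$gene_ids]
  dropped <- setdiff(panel, present)
  if (length(dropped))
    message("dropping ", length(dropped), " panel gene(s) absent externally: ",
            paste(dropped, collapse = ", "))
  if (length(present) == 0L) stop("no panel genes present in the external cohort")
  tests <- per_gene_tests(em_ext, y, present)
  gene_auc <- vapply(present, function(g) {
    a <- roc_auc(em_ext$values[g, ], y)$auc
    max(a, 1 - a)  # per-gene direction-free discriminability
  }, numeric(1L))
  cv <- loocv_classify(em_ext, y, present, seed = seed)
  structure(list(panel = present, dropped = dropped, tests = tests,
                 gene_auc = gene_auc, panel_auc = cv$auc, roc = cv$roc,
                 scores = cv$scores),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat(sprintf("Biomarker report: %d genes, panel AUC %.4f\n",
              length(x$panel), x$panel_auc))
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Export a z-scored panel submatrix with clustering orders for heatmaps
#'
#' Rows (genes) are z-scored; row and column orderings come from
#' average-linkage hierarchical clustering of Euclidean distances. With a
#' single gene only the column ordering is computed.
#'
#' @param em an [expression_matrix()].
#' @param panel character vector of gene ids.
#' @param path optional TSV output path for the reordered matrix.
#' @return list with `matrix` (z-scored, original order), `row_order`,
#'   `col_order` (integer permutations).
#' @export
export_heatmap_matrix <- function(em, panel, path = NULL) {
  stopifnot(inherits(em, "expr_matrix"), length(panel) >= 1L,
            all(panel %in% em$gene_ids))
  M <- em$values[panel, , drop = FALSE]
  mu <- rowMeans(M)
  s <- apply(M, 1L, sd)
  s[s == 0] <- 1
  Z <- sweep(sweep(M, 1L, mu), 1L, s, "/")
  row_order <- if (nrow(Z) > 1L) hclust(dist(Z), "average")$order
               else 1L
  col_order <- if (ncol(Z) > 1L) hclust(dist(t(Z)), "average")$order
               else 1L
  if (!is.null(path)) {
    out <- Z[row_order, col_order, drop = FALSE]
    write_tsv(data.frame(gene_id = rownames(out), out, check.names = FALSE),
              path)
  }
  list(matrix = Z, row_order = row_order, col_order = col_order)
}
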