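#' @export
print.deepgcfs <- function(x, ...) {
  cat("Graph-based ensemble biomarker selection\n")
  cat(sprintf("  genes: %d   samples: %d (%s)\n",
              nrow(x$expr$values), ncol(x$expr$values),
              paste(sprintf("%s=%d", names(table(x$expr$labels)),
                            table(x$expr$labels)), collapse = ", ")))
  cat(sprintf("  graph: %d edges (prune threshold %.4f)\n",
              n_edges(x$graph), x$threshold))
  cat(sprintf("  modules: k = %d\n", x$partition$k))
  cat(sprintf("  panel (%d genes): %s\n", nrow(x$panel),
              paste(x$panel$gene_id, collapse = ", ")))
  cat(sprintf("  leave-one-out panel AUC: %.4f\n", x$cv$auc))
  invisible(x)
}

#' Summary of a fitted biomarker selection
#'
#' @param object a [deepgcfs()] fit.
#' @param ... unused.
#' @return a `summary.deepgcfs` object: panel table with mutual
#'   information, per-gene p-values and AUCs, plus clustering metrics.
#' @export
summary.deepgcfs <- function(object, ...) {
  tab <- merge(object$panel, object$tests, by = "gene_id", sort = FALSE)
  tab$auc <- object$gene_auc[tab$gene_id]
  tab <- tab[order(-tab$mi, tab$gene_id), ]
  rownames(tab) <- NULL
  structure(list(panel = tab, k = object$partition$k,
                 metrics = object$metrics, panel_auc = object$cv$auc,
                 threshold = object$threshold,
                 edge_counts = object$edge_counts,
                 n_candidates = length(object$candidates$pooled)),
            class = "summary.deepgcfs")
}

#' @export
print.summary.deepgcfs <- function(x, ...) {
  cat(sprintf(
    "Modules: k = %d; pooled candidates: %d; prune threshold %.4f\n",
    x$k, x$n_candidates, x$threshold))
  if (!is.null(x$metrics))
    cat(sprintf("Embedding clustering: SI %.3f, CHI %.1f, DBI %.3f\n",
                x$metrics$SI, x$metrics$CHI, x$metrics$DBI))
  cat(sprintf("Panel AUC (pooled LOOCV): %.4f\n\n", x$panel_auc))
  print(x$panel, digits = 4)
  invisible(x)
}

#' Panel scores of a fit
#'
#' @param object a [deepgcfs()] fit.
#' @param ... unused.
#' @return named numeric vector: mutual information (nats) of each panel
#'   gene with the group label.
#' @export
coef.deepgcfs <- function(object, ...) {
  setNames(object$panel$mi, object$panel$gene_id)
}

#' Diagnostic plots for a fit
#'
#' `type = "roc"` draws the pooled leave-one-out ROC curve, `"loss"` the
#' training loss trace, `"heatmap"` the z-scored panel heatmap (base
#' graphics `image` with clustered orders).
#'
#' @param x a [deepgcfs()] fit.
#' @param type plot type.
#' @param ... passed to the underlying plotting function.
#' @return `x`, invisibly.
#' @export
plot.deepgcfs <- function(x, type = c("roc", "loss", "heatmap"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    graphics::plot(x$cv$roc$fpr, x$cv$roc$tpr, type = "s",
                   xlab = "False positive rate",
                   ylab = "True positive rate",
                   main = sprintf("Pooled LOOCV ROC (AUC %.3f)", x$cv$auc),
                   ...)
    graphics::abline(0, 1, lty = 2, col = "grey")
  } else if (type == "loss") {
    h <- x$embedding$loss_history
    graphics::plot(h$epoch, h$total, type = "l", xlab = "Epoch",
                   ylab = "Loss", main = "GNN training loss", ...)
  } else {
    hm <- export_heatmap_matrix(x$expr, x$panel$gene_id)
    M <- hm$matrix[hm$row_order, hm$col_order, drop = FALSE]
    graphics::image(t(M), axes = FALSE,
                    main = "Panel expression (z-scored)", ...)
  }
  invisible(x)
}

#' Score new samples with the fitted panel classifier
#'
#' Applies the depth-limited decision tree trained on the full fitting
#' cohort (restricted to the panel genes) to new samples.
#'
#' @param object a [deepgcfs()] fit.
#' @param newdata an [expression_matrix()] (or genes-x-samples matrix)
#'   containing the panel genes.
#' @param ... unused.
#' @return named numeric vector of positive-class probabilities.
#' @export
predict.deepgcfs <- function(object, newdata, ...) {
  if (is.null(object$classifier))
    stop("this fit carries no classifier (resumed from artifacts)")
  vals <- if (inherits(newdata, "expr_matrix")) newdata$values else newdata
  panel <- object$panel$gene_id
  missing <- setdiff(panel, rownames(vals))
  if (length(missing))
    stop("newdata lacks panel genes: ", paste(missing, collapse = ", "))
  df <- data.frame(t(vals[panel, , drop = FALSE]), check.names = FALSE)
  pos <- levels(object$expr$labels)[2L]
  p <- predict(object$classifier, newdata = df, type = "prob")[, pos]
  setNames(p, colnames(vals))
}
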