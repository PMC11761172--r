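## Subset a prior graph to a gene universe (edges with an endpoint outside
## are dropped).
subset_graph <- function(g, universe) {
  keep <- g$edges$from %in% universe & g$edges$to %in% universe
  e <- g$edges[keep, , drop = FALSE]
  gene_graph(if (nrow(e)) e else NULL, nodes = universe)
}

#' Fit the full biomarker-selection model
#'
#' Runs the complete pipeline on a labeled expression matrix: gene
#' filtering, co-expression graph construction merged with the prior
#' interaction graph, GNN embedding, hybrid module detection, ensemble
#' feature selection with rank aggregation, mutual-information panel
#' refinement, and in-cohort validation (per-gene tests, leave-one-out
#' decision-tree ROC/AUC). One global `seed` is fanned out deterministically
#' to every stochastic stage, so refitting with the same inputs reproduces
#' the result exactly.
#'
#' @param em an [expression_matrix()] with labels (or pass `labels`).
#' @param prior optional prior [gene_graph()]; edges outside the filtered
#'   gene universe are dropped.
#' @param labels optional labels overriding `em$labels`.
#' @param filter apply [filter_genes()] first (default `TRUE`).
#' @param cv_min,mean_min gene filter cutoffs.
#' @param threshold `"auto"` (maximal no-isolate threshold) or numeric.
#' @param absolute prune on absolute correlation.
#' @param gnn a [gnn_config()]; its `seed` is replaced by the stage seed
#'   derived from `seed`.
#' @param min_module_size,deep_split hybrid clustering parameters.
#' @param top_per_module candidates kept per module.
#' @param panel_size final panel size.
#' @param seed global integer seed.
#' @return an object of class `deepgcfs`; see [print.deepgcfs()],
#'   [summary.deepgcfs()], [coef.deepgcfs()], [plot.deepgcfs()],
#'   [predict.deepgcfs()].
#' @export
#' @examples
#' \donttest{
#' study <- synthetic_preset("easy", seed = 7)
#' fit <- deepgcfs(study$em, prior = study$prior,
#'                 gnn = gnn_config(epochs = 50), seed = 7)
#' print(fit)
#' }
deepgcfs <- function(em, prior = NULL, labels = NULL, filter = TRUE,
                     cv_min = 0.2, mean_min = 0, threshold = "auto",
                     absolute = FALSE, gnn = gnn_config(),
                     min_module_size = 30L, deep_split = 2L,
                     top_per_module = 10L, panel_size = 10L, seed = 1L) {
  cl <- match.call()
  stopifnot(inherits(em, "expr_matrix"))
  if (!is.null(labels)) em <- expression_matrix(em$values, labels = labels)
  if (is.null(em$labels)) stop("labels are required to fit the model")

  em_f <- if (filter) filter_genes(em, cv_min = cv_min, mean_min = mean_min)
          else em
  prior_f <- if (!is.null(prior)) subset_graph(prior, em_f$gene_ids)
             else NULL
  gb <- build_gene_graph(em_f, prior_f, threshold = threshold,
                         absolute = absolute)

  gnn$seed <- stage_seed(seed, "embed")
  emb <- train_embeddings(gb$graph, em_f, gnn)

  part <- hcm(emb$Z, min_module_size = min_module_size,
              seed = stage_seed(seed, "cluster"), deep_split = deep_split)
  metrics <- if (part$k >= 2L) clustering_indices(emb$Z, part) else NULL

  cand <- select_candidates(part, em_f, top_n = top_per_module,
                            seed = stage_seed(seed, "select"))
  panel <- mifs_refine(cand, em_f, panel_size = panel_size,
                       seed = stage_seed(seed, "refine"))

  tests <- per_gene_tests(em_f, panel = panel$gene_id)
  cv <- loocv_classify(em_f, panel = panel$gene_id,
                       seed = stage_seed(seed, "evaluate"))
  gene_auc <- vapply(panel$gene_id, function(g) {
    a <- roc_auc(em_f$values[g, ], em_f$labels)$auc
    max(a, 1 - a)
  }, numeric(1L))

  # full-data tree used by predict() on new cohorts
  set.seed(stage_seed(seed, "classifier"))
  df <- data.frame(t(em_f$values[panel$gene_id, , drop = FALSE]),
                   check.names = FALSE)
  df$.y <- em_f$labels
  classifier <- rpart::rpart(.y ~ ., data = df, method = "class",
                             control = rpart::rpart.control(
                               maxdepth = 3, cp = 0, minsplit = 4,
                               xval = 0))

  structure(
    list(call = cl, expr = em_f, graph = gb$graph,
         threshold = gb$threshold,
         edge_counts = c(expression = gb$n_expr_edges,
                         prior = gb$n_prior_edges,
                         merged = gb$n_merged_edges),
         embedding = emb, partition = part, metrics = metrics,
         candidates = cand, panel = panel, tests = tests, cv = cv,
         gene_auc = gene_auc, classifier = classifier,
         params = list(filter = filter, cv_min = cv_min,
                       mean_min = mean_min, threshold = threshold,
                       absolute = absolute, gnn = gnn,
                       min_module_size = min_module_size,
                       deep_split = deep_split,
                       top_per_module = top_per_module,
                       panel_size = panel_size, seed = seed)),
    class = "deepgcfs")
}

#' Run the pipeline from files or a config, writing every artifact
#'
#' Accepts either a YAML config path or a named list with entries `expr`,
#' `labels`, `prior` (file paths), `out_dir`, `seed` and optional parameter
#' overrides (`cv_min`, `mean_min`, `filter`, `threshold`, `absolute`,
#' `score_divisor`, `orientation`, `min_module_size`, `top_per_module`,
#' `panel_size`, and a `gnn` sublist of [gnn_config()] arguments).
#' Alternatively pass ready-made objects via `em` / `prior_graph`. Writes
#' `graph.tsv`, `Z.tsv`, `loss.csv`, `modules.tsv`, `metrics.json`,
#' `panel.json`, `report.json` and `run_log.txt` under `out_dir`. With
#' `resume = TRUE`, an existing `graph.tsv` / `Z.tsv` is reloaded instead of
#' recomputed (stage outputs are pure functions of inputs and config, so
#' regenerating a deleted artifact reproduces it exactly).
#'
#' @param config list or YAML file path.
#' @param em,prior_graph optional in-memory inputs overriding the paths.
#' @param resume reuse existing intermediate artifacts.
#' @return the fitted [deepgcfs] object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, em = NULL, prior_graph = NULL,
                         resume = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  if (is.null(em)) {
    stopifnot(!is.null(config$expr))
    labels <- if (!is.null(config$labels)) load_labels(config$labels)
    em <- load_expression_matrix(
      config$expr, orientation = config$orientation %||% "genes",
      missing_policy = config$missing_policy %||% "drop-gene",
      labels = labels)
  }
  gnn_args <- config$gnn %||% list()
  gnn <- do.call(gnn_config, gnn_args)
  filter <- config$filter %||% TRUE
  em_f <- if (isTRUE(filter)) {
    filter_genes(em, cv_min = config$cv_min %||% 0.2,
                 mean_min = config$mean_min %||% 0)
  } else em
  if (is.null(prior_graph) && !is.null(config$prior)) {
    prior_graph <- load_edge_list(config$prior, universe = em_f$gene_ids,
                                  score_divisor = config$score_divisor %||% 1)
  }

  log_path <- file.path(out, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  cat(sprintf("deepgcfs pipeline (package %s, R %s)\n",
              as.character(utils::packageVersion("deepgcfs")),
              getRversion()),
      file = log_path)
  logline("seed: %d", seed)

  graph_path <- file.path(out, "graph.tsv")
  z_path <- file.path(out, "Z.tsv")
  fit <- NULL
  if (resume && file.exists(graph_path) && file.exists(z_path)) {
    logline("resume: reusing %s and %s", graph_path, z_path)
    g <- load_edge_list(graph_path, universe = em_f$gene_ids)
    zdf <- read.delim(z_path, check.names = FALSE)
    Z <- as.matrix(zdf[, -1L, drop = FALSE])
    rownames(Z) <- as.character(zdf[[1L]])
    fit <- finish_fit_from_embedding(em_f, g, Z, config, seed)
  } else {
    fit <- deepgcfs(em_f, prior = prior_graph, filter = FALSE,
                    threshold = config$threshold %||% "auto",
                    absolute = isTRUE(config$absolute), gnn = gnn,
                    min_module_size = config$min_module_size %||% 30L,
                    deep_split = config$deep_split %||% 2L,
                    top_per_module = config$top_per_module %||% 10L,
                    panel_size = config$panel_size %||% 10L, seed = seed)
    write_edge_list(fit$graph, graph_path)
    write_embeddings(fit$embedding, z_path)
    write_tsv(fit$embedding$loss_history, file.path(out, "loss.csv"))
  }

  write_tsv(data.frame(gene_id = fit$partition$gene_ids,
                       module = as.integer(fit$partition$module_of)),
            file.path(out, "modules.tsv"))
  jsonlite::write_json(
    c(list(k = fit$partition$k), fit$metrics),
    file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(panel = fit$panel,
         pooled_candidates = fit$candidates$pooled,
         per_module = lapply(fit$candidates$per_module, identity),
         params = list(seed = seed,
                       threshold = fit$threshold,
                       min_module_size = fit$params$min_module_size,
                       top_per_module = fit$params$top_per_module,
                       panel_size = fit$params$panel_size)),
    file.path(out, "panel.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(panel = fit$panel$gene_id,
         panel_auc = fit$cv$auc,
         gene_auc = as.list(fit$gene_auc),
         tests = fit$tests,
         roc = fit$cv$roc,
         threshold = fit$threshold,
         edge_counts = as.list(fit$edge_counts),
         k = fit$partition$k,
         params = fit$params[setdiff(names(fit$params), "gnn")]),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
  logline("threshold: %.6f; edges: %d; k: %d; panel AUC: %.4f",
          fit$threshold, n_edges(fit$graph), fit$partition$k, fit$cv$auc)
  invisible(fit)
}

## Complete the downstream stages from a reloaded graph + embedding.
finish_fit_from_embedding <- function(em_f, g, Z, config, seed) {
  part <- hcm(Z, min_module_size = config$min_module_size %||% 30L,
              seed = stage_seed(seed, "cluster"),
              deep_split = config$deep_split %||% 2L)
  metrics <- if (part$k >= 2L) clustering_indices(Z, part) else NULL
  cand <- select_candidates(part, em_f,
                            top_n = config$top_per_module %||% 10L,
                            seed = stage_seed(seed, "select"))
  panel <- mifs_refine(cand, em_f, panel_size = config$panel_size %||% 10L,
                       seed = stage_seed(seed, "refine"))
  tests <- per_gene_tests(em_f, panel = panel$gene_id)
  cv <- loocv_classify(em_f, panel = panel$gene_id,
                       seed = stage_seed(seed, "evaluate"))
  gene_auc <- vapply(panel$gene_id, function(gn) {
    a <- roc_auc(em_f$values[gn, ], em_f$labels)$auc
    max(a, 1 - a)
  }, numeric(1L))
  structure(
    list(call = NULL, expr = em_f, graph = g, threshold = NA_real_,
         edge_counts = c(expression = NA, prior = NA,
                         merged = n_edges(g)),
         embedding = list(Z = Z), partition = part, metrics = metrics,
         candidates = cand, panel = panel, tests = tests, cv = cv,
         gene_auc = gene_auc, classifier = NULL,
         params = list(seed = seed,
                       min_module_size = config$min_module_size %||% 30L,
                       top_per_module = config$top_per_module %||% 10L,
                       panel_size = config$panel_size %||% 10L)),
    class = "deepgcfs")
}
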