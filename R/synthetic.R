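#' Generate a two-group synthetic expression cohort with planted structure
#'
#' Emulates a small case/control transcriptomic study: `k_modules` blocks of
#' co-expressed genes built from a shared latent factor
#' (`x = sqrt(w) * f + sqrt(1 - w) * noise_sd * eps`, whose population
#' within-module correlation is `w / (w + (1 - w) * noise_sd^2)`, exactly
#' `w` at the default unit noise), independent background genes, and
#' `n_diff` discriminative genes spread round-robin across the modules whose
#' case samples are shifted by `effect_size` gene standard deviations. Every
#' gene receives a positive baseline (uniform on 2-4) so mean/CV filtering
#' is well defined. Fully reproducible: identical seeds give byte-identical
#' output.
#'
#' @param n_genes total genes.
#' @param n_samples_case,n_samples_control group sizes (defaults 20 / 10,
#'   a typical small hypertension cohort design).
#' @param k_modules number of planted modules.
#' @param module_size genes per module (`k_modules * module_size <=
#'   n_genes`; the remainder are background).
#' @param within_r latent-factor share `w` in (0, 1); equals the population
#'   within-module correlation at `noise_sd = 1`.
#' @param n_diff number of discriminative genes (`<= n_genes`).
#' @param diff_genes optional character vector fixing the discriminative
#'   gene identities (for external cohorts drawn from the same generative
#'   truth); overrides `n_diff`.
#' @param effect_size case-group mean shift in units of the gene sd.
#' @param noise_sd sd multiplier of the idiosyncratic noise.
#' @param seed integer seed.
#' @return list with `em` (an [expression_matrix()] with labels
#'   `control`/`case`) and `truth` (list: `module_of` named integer, 0 =
#'   background; `diff_genes`; `params`).
#' @export
generate_cohort <- function(n_genes, n_samples_case = 20L,
                            n_samples_control = 10L, k_modules = 3L,
                            module_size = 40L, within_r = 0.7,
                            n_diff = 10L, effect_size = 2,
                            noise_sd = 1, seed = 1L, diff_genes = NULL) {
  stopifnot(k_modules * module_size <= n_genes, n_diff <= n_genes,
            n_samples_case >= 2L, n_samples_control >= 2L)
  if (within_r <= 0 || within_r >= 1) stop("within_r must be in (0, 1)")
  set.seed(as.integer(seed))
  n <- n_samples_case + n_samples_control
  is_case <- c(rep(FALSE, n_samples_control), rep(TRUE, n_samples_case))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- c(sprintf("ctrl%02d", seq_len(n_samples_control)),
                  sprintf("case%02d", seq_len(n_samples_case)))
  module_of <- rep(0L, n_genes)
  for (m in seq_len(k_modules))
    module_of[(m - 1L) * module_size + seq_len(module_size)] <- m
  names(module_of) <- gene_ids

  f <- matrix(rnorm(k_modules * n), k_modules, n)  # latent factor per module
  X <- matrix(0, n_genes, n, dimnames = list(gene_ids, sample_ids))
  w <- within_r
  for (g in seq_len(n_genes)) {
    eps <- rnorm(n, sd = noise_sd)
    X[g, ] <- if (module_of[g] > 0L) {
      sqrt(w) * f[module_of[g], ] + sqrt(1 - w) * eps
    } else {
      eps
    }
  }

  # discriminative genes: fixed identities if supplied, otherwise spread
  # round-robin over the modules, sampled within each module
  if (!is.null(diff_genes)) {
    stopifnot(all(diff_genes %in% gene_ids))
    n_diff <- length(diff_genes)
  } else if (n_diff > 0L) {
    if (k_modules > 0L) {
      per_mod <- tabulate(rep(seq_len(k_modules), length.out = n_diff),
                          k_modules)
      diff_genes <- unlist(lapply(seq_len(k_modules), function(m) {
        pool <- gene_ids[module_of == m]
        sample(pool, min(per_mod[m], length(pool)))
      }))
    } else {
      diff_genes <- sample(gene_ids, n_diff)
    }
  } else {
    diff_genes <- character(0)
  }
  if (length(diff_genes)) {
    sd_theory <- ifelse(module_of[diff_genes] > 0L,
                        sqrt(w + (1 - w) * noise_sd^2), noise_sd)
    X[diff_genes, is_case] <- X[diff_genes, is_case] +
      effect_size * sd_theory
  }

  baseline <- runif(n_genes, 2, 4)
  X <- X + baseline
  labels <- factor(ifelse(is_case, "case", "control"),
                   levels = c("control", "case"))
  names(labels) <- sample_ids
  em <- expression_matrix(X, labels = labels)
  truth <- list(module_of = module_of, diff_genes = sort(diff_genes),
                effect_size = effect_size,
                params = list(n_genes = n_genes,
                              n_samples_case = n_samples_case,
                              n_samples_control = n_samples_control,
                              k_modules = k_modules,
                              module_size = module_size,
                              within_r = within_r, n_diff = n_diff,
                              effect_size = effect_size,
                              noise_sd = noise_sd, seed = seed))
  list(em = em, truth = truth)
}

#' Generate a noisy prior interaction graph matching planted modules
#'
#' Each within-module gene pair receives an edge with probability
#' `p_within`, each remaining pair with probability `p_between`; edge
#' weights are uniform on (0.4, 1), mimicking a medium-confidence
#' interaction-score export.
#'
#' @param truth the `truth` element of [generate_cohort()].
#' @param p_within,p_between edge probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return a [gene_graph()] over all genes of the cohort.
#' @export
generate_prior_edges <- function(truth, p_within = 0.3, p_between = 0.01,
                                 seed = 1L) {
  stopifnot(p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1)
  set.seed(as.integer(seed))
  mod <- truth$module_of
  ids <- names(mod)
  n <- length(ids)
  pr <- utils::combn(n, 2L)
  same <- mod[pr[1L, ]] > 0L & mod[pr[1L, ]] == mod[pr[2L, ]]
  p <- ifelse(same, p_within, p_between)
  keep <- runif(ncol(pr)) < p
  if (!any(keep)) return(gene_graph(NULL, nodes = ids))
  i <- pr[1L, keep]; j <- pr[2L, keep]
  edges <- data.frame(from = ids[i], to = ids[j],
                      weight = runif(sum(keep), 0.4, 1),
                      stringsAsFactors = FALSE)
  gene_graph(edges, nodes = ids)
}

#' Named synthetic study presets
#'
#' `easy`: 300 genes, 3 modules of 90 (30 background), within-module
#' correlation 0.7, 10 discriminative genes with a 2-sd shift, 20 case / 10
#' control samples. `hard`: weaker correlation (0.5) and a 1-sd shift over
#' 500 genes. `null`: the easy design with a zero effect (no discriminative
#' signal).
#'
#' @param preset one of `"easy"`, `"hard"`, `"null"`.
#' @param seed integer seed; the cohort and prior derive their own stage
#'   seeds from it.
#' @param p_within,p_between prior edge probabilities.
#' @return list with `em`, `truth`, `prior`.
#' @export
synthetic_preset <- function(preset = c("easy", "hard", "null"), seed = 1L,
                             p_within = 0.3, p_between = 0.01) {
  preset <- match.arg(preset)
  args <- switch(preset,
    easy = list(n_genes = 300L, k_modules = 3L, module_size = 90L,
                within_r = 0.7, n_diff = 10L, effect_size = 2),
    hard = list(n_genes = 500L, k_modules = 3L, module_size = 150L,
                within_r = 0.5, n_diff = 10L, effect_size = 1),
    null = list(n_genes = 300L, k_modules = 3L, module_size = 90L,
                within_r = 0.7, n_diff = 10L, effect_size = 0))
  cohort <- do.call(generate_cohort,
                    c(args, list(seed = stage_seed(seed, "cohort"))))
  prior <- generate_prior_edges(cohort$truth, p_within = p_within,
                                p_between = p_between,
                                seed = stage_seed(seed, "prior"))
  list(em = cohort$em, truth = cohort$truth, prior = prior)
}

#' Write a synthetic study to disk
#'
#' Writes `expr.tsv`, `labels.tsv`, `prior.tsv` and `truth.json` under
#' `out_dir`.
#'
#' @param study a [synthetic_preset()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(study$em, file.path(out_dir, "expr.tsv"))
  write_tsv(data.frame(sample_id = study$em$sample_ids,
                       label = as.character(study$em$labels)),
            file.path(out_dir, "labels.tsv"))
  write_edge_list(study$prior, file.path(out_dir, "prior.tsv"))
  jsonlite::write_json(
    list(module_of = as.list(study$truth$module_of),
         diff_genes = study$truth$diff_genes,
         params = study$truth$params),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
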