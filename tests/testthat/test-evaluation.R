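test_that("per-gene tests reproduce exact and textbook p-values", {
  # identical group values: t = 0, p = 1
  X <- rbind(g1 = c(1, 2, 3, 1, 2, 3))
  em <- make_em(X, labels = c(0, 0, 0, 1, 1, 1))
  res <- per_gene_tests(em)
  expect_equal(res$p_t, 1)
  # fully separated 3 vs 3: the exact two-sided rank-sum level is 0.1
  em2 <- make_em(rbind(g1 = c(1, 2, 3, 101, 102, 103)),
                 labels = c(0, 0, 0, 1, 1, 1))
  expect_equal(per_gene_tests(em2)$p_w, 0.1)
  # Welch p equals the textbook formula on random draws
  set.seed(43)
  for (rep in 1:5) {
    a <- rnorm(10); b <- rnorm(10, 0.5, 1.4)
    em3 <- make_em(rbind(g = c(a, b)), labels = rep(c(0, 1), each = 10))
    expect_equal(per_gene_tests(em3)$p_t, oracle_welch_p(a, b),
                 tolerance = 1e-10)
  }
  # order permutation invariance
  set.seed(44)
  X4 <- matrix(rnorm(3 * 20), 3, 20,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:20)))
  y4 <- rep(c(0, 1), each = 10)
  em4 <- make_em(X4, labels = y4)
  perm <- sample(20)
  em5 <- make_em(X4[, perm], labels = y4[perm])
  expect_equal(per_gene_tests(em4)[c("p_t", "p_w")],
               per_gene_tests(em5)[c("p_t", "p_w")])
  # degenerate gene: zero variance in both groups
  em6 <- make_em(rbind(g = rep(2, 8)), labels = rep(c(0, 1), each = 4))
  r6 <- per_gene_tests(em6)
  expect_true(r6$degenerate)
  expect_equal(r6$p_t, 1)
})

test_that("threshold-sweep AUC equals all-pairs counting", {
  expect_equal(roc_auc(c(1, 2, 9, 10), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(tail(r$roc$tpr, 1), 1)
  expect_true(all(diff(r$roc$fpr) >= 0))
  set.seed(47)
  for (rep in 1:100) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))  # rounding makes ties likely
    expect_equal(roc_auc(s, y)$auc, oracle_auc(s, y), tolerance = 1e-12)
  }
  # complementarity on tie-free scores
  set.seed(48)
  s <- rnorm(12); y <- rep(c(0, 1), 6)
  expect_equal(roc_auc(s, y)$auc + roc_auc(-s, y)$auc, 1)
})

test_that("our AUC agrees with pROC", {
  set.seed(49)
  s <- rnorm(30); y <- rbinom(30, 1, 0.5); y[1:2] <- 0:1
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, s,
                                                         direction = "<"))))
  expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("leave-one-out classification discriminates a planted cohort", {
  co <- generate_cohort(n_genes = 40L, k_modules = 2L, module_size = 15L,
                        within_r = 0.6, n_diff = 10L, effect_size = 2,
                        seed = 1)
  panel <- co$truth$diff_genes
  cv <- loocv_classify(co$em, panel = panel, seed = 1)
  expect_gte(cv$auc, 0.9)
  expect_length(cv$scores, 30L)
  # determinism
  cv2 <- loocv_classify(co$em, panel = panel, seed = 1)
  expect_identical(cv$scores, cv2$scores)
  # permuted labels give chance-level AUC
  set.seed(54)
  null_auc <- replicate(10, {
    yp <- sample(as.vector(co$em$labels))
    loocv_classify(co$em, y = yp, panel = panel, seed = 1)$auc
  })
  expect_true(all(null_auc >= 0.1 & null_auc <= 0.9))
  expect_true(median(null_auc) > 0.2 & median(null_auc) < 0.8)
})

test_that("external validation handles identity and missing genes", {
  co <- generate_cohort(n_genes = 30L, k_modules = 2L, module_size = 10L,
                        within_r = 0.6, n_diff = 6L, effect_size = 2,
                        seed = 59)
  panel <- co$truth$diff_genes
  rep_in <- loocv_classify(co$em, panel = panel, seed = 3)
  ext <- external_validate(co$em, panel = panel, seed = 3)
  expect_equal(ext$panel_auc, rep_in$auc)
  # a panel gene absent from the external cohort is reported and dropped
  em_small <- make_em(co$em$values[setdiff(co$em$gene_ids, panel[1]), ],
                      labels = co$em$labels)
  expect_message(ext2 <- external_validate(em_small, panel = panel,
                                           seed = 3),
                 "absent")
  expect_equal(ext2$dropped, panel[1])
  expect_length(ext2$panel, length(panel) - 1L)
  expect_true(is.finite(ext2$panel_auc))
})

test_that("a planted panel generalizes to an external cohort from the same truth", {
  co <- generate_cohort(n_genes = 60L, k_modules = 3L, module_size = 18L,
                        within_r = 0.7, n_diff = 10L, effect_size = 2,
                        seed = 67)
  ext <- generate_cohort(n_genes = 60L, k_modules = 3L, module_size = 18L,
                         within_r = 0.7, effect_size = 2,
                         diff_genes = co$truth$diff_genes, seed = 68)
  expect_identical(ext$truth$diff_genes, co$truth$diff_genes)
  rep_ext <- external_validate(ext$em, panel = co$truth$diff_genes,
                               seed = 2)
  expect_gte(rep_ext$panel_auc, 0.85)
})

test_that("heatmap export z-scores rows and returns permutations", {
  co <- generate_cohort(n_genes = 12L, k_modules = 2L, module_size = 5L,
                        within_r = 0.6, n_diff = 4L, seed = 61)
  hm <- export_heatmap_matrix(co$em, co$em$gene_ids[1:6])
  expect_equal(unname(rowMeans(hm$matrix)), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(apply(hm$matrix, 1, sd)), rep(1, 6),
               tolerance = 1e-10)
  expect_setequal(hm$row_order, 1:6)
  expect_setequal(hm$col_order, seq_len(ncol(co$em$values)))
  hm1 <- export_heatmap_matrix(co$em, co$em$gene_ids[1])
  expect_equal(nrow(hm1$matrix), 1L)
  expect_equal(hm1$row_order, 1L)
})
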