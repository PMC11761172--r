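# Shared labeled instance: 24 samples, one perfect separator among noise.
sep_instance <- function(seed = 1, n = 24, p = 6) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("g%02d", seq_len(p))))
  y <- rep(c(0, 1), each = n / 2)
  X[, "g03"] <- y  # exactly the label
  list(X = X, y = y)
}

test_that("a perfect separator tops the informative evaluators", {
  inst <- sep_instance(1)
  for (ev in c("ANOVA", "MIFS", "DT", "MIC", "ReliefF")) {
    rl <- rank_genes(ev, inst$X, inst$y, seed = 1)
    expect_equal(rl$gene_ids[1], "g03")
  }
})

test_that("every evaluator returns a deterministic permutation", {
  inst <- sep_instance(2)
  for (ev in evaluator_names()) {
    r1 <- rank_genes(ev, inst$X, inst$y, seed = 5)
    r2 <- rank_genes(ev, inst$X, inst$y, seed = 5)
    expect_setequal(r1$gene_ids, colnames(inst$X))
    expect_identical(r1$gene_ids, r2$gene_ids)
  }
  # all-identical columns fall back to the ascending-id tie rule
  Xc <- matrix(rep(rnorm(20), 4), 20, 4,
               dimnames = list(NULL, c("d", "b", "a", "c")))
  y <- rep(c(0, 1), each = 10)
  rl <- rank_genes("ANOVA", Xc, y)
  expect_identical(rl$gene_ids, c("a", "b", "c", "d"))
  expect_error(rank_genes("ANOVA", Xc, rep(0, 20)), "2 classes")
})

test_that("ANOVA scores equal the F statistic from aov", {
  set.seed(3)
  X <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  y <- rep(c(0, 1), each = 10)
  rl <- rank_genes("ANOVA", X, y)
  f_ref <- sapply(colnames(X), function(g)
    summary(aov(X[, g] ~ factor(y)))[[1]]$`F value`[1])
  expect_equal(rl$scores, unname(sort(f_ref, decreasing = TRUE)),
               tolerance = 1e-8)
})

test_that("rank aggregation follows the beta order-statistic score", {
  # single list: identity
  rl <- list(structure(list(evaluator = "x",
                            gene_ids = c("c", "a", "b"),
                            scores = 3:1), class = "ranked_list"))
  expect_equal(rra_aggregate(rl)$gene_id, c("c", "a", "b"))
  # unanimous top over m = 10 lists of n = 50: every normalized rank is
  # 1/50, so the minimum over k of the order-statistic tails is attained at
  # k = m with the closed form (1/50)^10
  genes <- sprintf("g%02d", 1:50)
  set.seed(19)
  lists <- replicate(10, c("g01", sample(genes[-1])), simplify = FALSE)
  agg <- rra_aggregate(lists)
  expect_equal(agg$gene_id[1], "g01")
  expect_equal(agg$rho[1], (1 / 50)^10, tolerance = 1e-10)
  # exchangeability: relabeling/reordering the lists changes nothing
  agg2 <- rra_aggregate(rev(lists))
  expect_identical(agg, agg2)
  # mismatched gene sets are rejected
  expect_error(rra_aggregate(list(c("a", "b"), c("a", "c"))), "permutations")
})

test_that("agreeing evidence cannot demote a consensus top gene", {
  genes <- sprintf("g%02d", 1:20)
  set.seed(23)
  for (rep in 1:10) {
    lists <- replicate(5, c("g01", sample(genes[-1])), simplify = FALSE)
    base_rank <- match("g01", rra_aggregate(lists)$gene_id)
    more <- c(lists, list(c("g01", sample(genes[-1]))))
    new_rank <- match("g01", rra_aggregate(more)$gene_id)
    expect_lte(new_rank, base_rank)
  }
})

test_that("random rank vectors score far worse than unanimous ones", {
  genes <- sprintf("g%02d", 1:50)
  unanimous <- rra_aggregate(replicate(10, c("g01", sample(genes[-1])),
                                       simplify = FALSE))$rho[1]
  set.seed(29)
  null_rhos <- replicate(200, {
    lists <- replicate(10, sample(genes), simplify = FALSE)
    agg <- rra_aggregate(lists)
    agg$rho[agg$gene_id == "g01"]
  })
  expect_true(all(null_rhos > unanimous))
  expect_gt(median(null_rhos), 1e-6)
})

test_that("candidate selection honors per-module counts", {
  co <- generate_cohort(n_genes = 36L, k_modules = 3L, module_size = 12L,
                        within_r = 0.6, n_diff = 3L, effect_size = 2,
                        seed = 31)
  p <- module_partition(co$em$gene_ids, co$truth$module_of)
  cand <- select_candidates(p, co$em, top_n = 10L, seed = 1)
  expect_length(cand$pooled, 30L)
  expect_false(anyDuplicated(cand$pooled) > 0)
  # a module smaller than top_n contributes all of its genes
  small <- c(rep(1L, 4), rep(2L, 32))
  p2 <- module_partition(co$em$gene_ids, small)
  cand2 <- select_candidates(p2, co$em, top_n = 10L, seed = 1)
  expect_length(cand2$pooled, 14L)
})

test_that("mutual-information refinement ranks label-matching genes first", {
  set.seed(37)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
  X["g4", ] <- y
  em <- make_em(X, labels = y)
  panel <- mifs_refine(c("g1", "g2", "g3", "g4", "g5"), em, panel_size = 2)
  expect_equal(panel$gene_id[1], "g4")
  expect_equal(panel$mi[1], deepgcfs:::entropy_nats(y))
  # determinism
  panel2 <- mifs_refine(c("g1", "g2", "g3", "g4", "g5"), em, panel_size = 2)
  expect_identical(panel, panel2)
  expect_error(mifs_refine(c("g1", "g2"), em, panel_size = 5), "exceeds")
})

test_that("the MI estimate of an independent gene is near zero", {
  set.seed(41)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  mis <- replicate(20, deepgcfs:::mutual_information(rnorm(n), y,
                                                     seed = sample.int(1e6, 1)))
  expect_lt(median(mis), 0.05)
  expect_lt(max(mis), 0.1)
})
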