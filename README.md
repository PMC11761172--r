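# deepgcfs

Selection of small gene-expression biomarker panels for two-group
(case/control) transcriptomic studies, for analysts who have a normalized
expression matrix, binary sample labels, and optionally a prior gene–gene
interaction edge list (e.g. a STRING export).

Univariate differential testing on small cohorts ignores the dependency
structure among genes. This package instead:

1. **builds a weighted gene graph** — Pearson co-expression pruned at the
   largest threshold `t* = min_i max_{j≠i} r_ij` that leaves no isolated
   gene, merged with the prior graph (shared edge → mean weight, unique
   edge → half weight);
2. **learns a d-dimensional embedding per gene** with a three-layer
   weighted-aggregation graph neural network: each layer aggregates a
   sampled neighborhood as a convex combination (edge weights normalized to
   sum to 1), concatenates the self state, and applies a linear map + ReLU
   with batch normalization and dropout. Training minimizes
   `L = L_link + L_rec`, a balanced link-prediction cross-entropy on
   sampled edge/non-edge pairs (batch positives are removed from the
   message graph) plus the cross-entropy between `sigmoid(Z Zᵀ)` and the
   adjacency indicator over all ordered pairs;
3. **detects gene modules** by a hybrid: a dynamic cut of the
   average-linkage dendrogram of `1 − cor(Z)` fixes the module count k
   (minimum module size 30), then k-means assigns genes;
4. **ranks genes within each module** by ten evaluators (MIFS, MIC, ANOVA,
   ReliefF, GBDT, RF, lasso, ridge, linear regression, decision tree),
   fuses the rankings with robust rank aggregation
   (`rho = min_k P(Beta(k, m−k+1) ≤ r_(k))`), pools the top 10 per module
   and refines to the final 10-gene panel by mutual information with the
   label;
5. **validates the panel**: Welch t and Wilcoxon rank-sum tests per gene,
   pooled leave-one-out ROC/AUC with a depth-3 decision tree, and optional
   external-cohort validation.

A seeded synthetic-cohort generator with planted modules and
discriminative genes (`generate_cohort()`, `synthetic_preset()`) makes the
whole pipeline testable without any downloads.

## Worked example

```r
library(deepgcfs)

study <- synthetic_preset("easy", seed = 7)   # 300 genes, 3 modules, 20/10 samples
fit <- deepgcfs(study$em, prior = study$prior, seed = 7)
print(fit)
```

```
Graph-based ensemble biomarker selection
  genes: 292   samples: 30 (control=10, case=20)
  graph: 12269 edges (prune threshold 0.2880)
  modules: k = 3
  panel (10 genes): G0044, G0054, G0059, G0120, G0159, G0218, G0043, G0138, G0015, G0116
  leave-one-out panel AUC: 0.9000
```

The gene filter kept 292 of 300 genes (CV > 0.2), the auto-pruned
co-expression graph merged with the prior has 12,269 edges, the dynamic
cut found the three planted modules, and the final panel classifies the
held-out samples with AUC 0.90. `summary(fit)` adds per-gene statistics:

```
   gene_id     mi       p_t       p_w degenerate     fdr_t     fdr_w   auc
1    G0044 0.5092 3.325e-05 2.436e-05      FALSE 6.806e-05 6.091e-05 0.935
2    G0054 0.4078 4.655e-06 1.791e-05      FALSE 2.327e-05 6.091e-05 0.940
...
```

`mi` is each gene's mutual information with the label (nats), `p_t`/`p_w`
the uncorrected two-sided Welch and rank-sum p-values, `auc` the
single-gene direction-free AUC. Eight of the ten panel genes here are the
planted discriminative genes (`study$truth$diff_genes`). Further methods:
`coef(fit)` (panel MI scores), `plot(fit, type = "roc" | "loss" |
"heatmap")`, `predict(fit, new_expression_matrix)`, and
`external_validate()` for an independent cohort.

`run_pipeline()` performs the same fit from file inputs or a YAML config
and writes every intermediate (`graph.tsv`, `Z.tsv`, `modules.tsv`,
`metrics.json`, `panel.json`, `report.json`, run log). A thin CLI over the
same functions is at `inst/cli/deepgcfs.R`
(`simulate`, `build-graph`, `embed`, `cluster`, `select`, `evaluate`,
`validate-external`, `run-all`).

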