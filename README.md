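# striamic

Acute severe stress leaves a lasting mark on the brain's resident immune
cells. In rats, a single session of inescapable tail-shock suppresses
voluntary wheel running for weeks, and single-nucleus RNA-seq of the
striatum shows that striatal microglia remain transcriptionally activated
long after the stressor — an activation state not captured by the classic
M1/M2 dichotomy. striamic re-implements that study's analysis pipeline as a
tested, reusable R package, exercised end-to-end on synthetic data that
emulates the study design (no public accession exists for the original
counts).

The package is for computational biologists who want the individual pieces
of such an analysis as auditable functions: barcode-level QC, count
normalisation, graph clustering with a principled choice of resolution,
donor-aware differential expression, per-cell gene-set scores, and causal
mediation between treatment, expression and behaviour.

## What's inside

* **Synthetic cohort generator** (`generate_dataset()`): 4 groups
  (stress x wheel) x 6 individuals, NB counts with per-gene dispersion
  `theta`, lognormal libraries, planted marker-gene clusters, a
  transcriptional-breadth maturity gradient, treatment log-fold effects,
  planted QC violators, and a running model in which stress suppresses
  6-week distance to 14.9% of control.
* **QC** (`apply_qc_filters()`): keep barcodes with >= 750 UMIs, >= 500
  genes, <= 20,000 UMIs, <= 5000 genes, <= 5% mitochondrial content;
  removals attributed to the first violated rule.
* **Clustering** (`normalize_residuals()`, `pca_embed()`,
  `build_snn_graph()`, `community_detect()`): Gamma-Poisson Pearson
  residuals, 50 PCs, SNN graph (k = 50, Jaccard weights), Louvain.
* **Resolution selection** (`build_kmst()`, `within_edge_count_z()`,
  `select_resolution()`): the union of k orthogonal minimum spanning trees
  scores each candidate clustering by its standardized within-cluster edge
  count

  `Z = (R_W - E[R_W]) / sqrt(Var[R_W])`,

  with exact permutation-null moments (cluster sizes fixed); the resolution
  maximising Z is selected.
* **Maturity** (`maturity_score()`, `compare_maturity()`): a
  transcriptional-diversity score in [0, 1] (higher = broader expression =
  less differentiated), compared across clusters by a linear mixed model
  with the individual as random intercept.
* **Differential expression** (`estimate_dispersions()`, `fit_nb_glmm()`,
  `de_test_all()`): per-gene NB mixed model
  `log mu = offset + X beta + b_individual`, Laplace-approximation ML with
  fixed Gamma-Poisson dispersion, small-sample-corrected Wald t tests, and
  Storey q-values (`storey_qvalues()`); plus Wilcoxon marker tests,
  hypergeometric overlap tests, Fisher over-representation and preranked
  GSEA over user-supplied GMT sets.
* **State scores** (`state_scores()`, `score_lmm()`,
  `composition_tests()`, `updown_gof()`): M1/M2/metabolism raw-count
  proportions per nucleus, mixed-model score comparisons, chi-square and
  pairwise Fisher composition tests, and the 1-df up/down goodness-of-fit
  chi-square.
* **Mediation** (`mediate()`, `screen_mediators()`): linear two-equation
  mediation (ACME = a*b, ADE = c') with percentile bootstrap CIs, and a
  two-direction screen separating genes that mediate the stress ->
  running deficit from genes that respond to running.

The `analysis/` directory holds numbered driver scripts
(`01_simulate.R` … `07_mediation.R`) that run the full workflow over a
simulated cohort and write tables under `results/`.

## Worked example

```r
library(striamic)

# a 100-barcode fixture with planted QC violators: 5 low-UMI, 3 low-gene,
# 2 high-UMI, 1 high-mito
d <- generate_dataset(qc_fixture_config(seed = 1))
qc <- apply_qc_filters(d$counts)
print(qc$report)
#> QC filter report: 89 of 100 barcodes kept
#> removed by rule (first-violated attribution):
#>   min_umi min_genes   max_umi max_genes      mito
#>         5         3         2         0         1

# the published up/down asymmetry statistic: 21 up vs 3 down
g <- updown_gof(21, 3)
sprintf("chisq = %.1f, p = %.2e", g$chisq, g$p)
#> "chisq = 13.5, p = 2.39e-04"

# cluster a planted 3-population cohort and pick the resolution by the
# K-MST standardized within-cluster edge count
d2 <- generate_dataset(synth_config(n_genes = 800, n_nuclei = 1500,
  n_clusters = 3, marker_log2fc = 2, maturity_gradient = FALSE, seed = 7))
res  <- normalize_residuals(d2$counts)
emb  <- pca_embed(res, n_components = 50, seed = 1)
snn  <- build_snn_graph(emb, k = 50)
scan <- select_resolution(emb, snn, grid = seq(0.1, 1, 0.1), seed = 1)
sprintf("resolution %.1f -> %d clusters, Z = %.1f",
        scan$selected_resolution,
        length(unique(scan$selected_labels)), max(scan$scan$Z))
#> "resolution 0.1 -> 3 clusters, Z = 122.1"
```

The 89/100 survivors are exact arithmetic on the planted violators; the
chi-square reproduces the published statistic for 21 up- versus 3
down-regulated stress genes; and the resolution scan recovers the three
planted populations (adjusted Rand index vs truth > 0.99 on this fixture).

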