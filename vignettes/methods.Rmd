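---
title: "Models and methods in striamic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in striamic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

striamic re-implements, as tested and reusable functions, a single-nucleus
RNA-seq analysis of striatal microglia under a 2 x 2 design of acute stress
and voluntary wheel running. This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
that were genuinely open.

## The synthetic cohort

No public accession exists for the data the pipeline targets, so every
stage is exercised on synthetic data with known ground truth. The generator
(`generate_dataset()`) draws counts from the same family of models the
downstream analyses assume:

* **Design.** Four groups — sedentary/no-stress, runner/no-stress,
  sedentary/stress, runner/stress — with 6 individuals each. Nuclei are
  assigned to individuals at random, emulating pooled captures.
* **Counts.** For nucleus $c$ of individual $i$ the mean of gene $g$ is
  $\mu_{gc} = L_c\,e^{u_i}\,p_{g(c)}$, where $L_c$ is a lognormal library
  size (median about 2000 UMIs, matching the reported per-pool medians of
  1877–2197), $u_i \sim N(0, \sigma_u^2)$ is an individual intercept, and
  $p_{g(c)}$ is a softmax over genes of a base profile plus cluster-marker
  boosts and treatment log-fold effects. Counts are negative binomial with
  gene-specific dispersion $\theta_g \sim U(0.5, 10)$. Zero inflation is
  deliberately absent: the downstream model is NB, and the tests should
  measure that model under its own assumptions.
* **Individual intercepts.** $u_i$ multiplies every gene of a nucleus
  identically. Placed inside the softmax it would cancel, so it acts on the
  realised library size; the truth table records $L_c e^{u_i}$ as the
  planted library so the column-sum invariant is exact. A consequence worth
  stating plainly: in the full generator the donor effect is absorbed by
  the log-library offset, so gene-level donor variability is simulated
  separately by `simulate_nb_gene()`, which gives each gene its own
  $u_{ig}$. The differential-expression calibration studies use the
  gene-level simulator; the pipeline-level recall study uses the full
  generator.
* **Maturity gradient.** Each nucleus has a latent rank $r \in [0,1]$; it
  expresses the top fraction (0.4–0.95) of genes in a fixed
  abundance order, plus its own cluster's markers and the mitochondrial
  genes. Breadth of expression is therefore nested, which is what a
  transcriptional-diversity score can recover.
* **Running model.** Per-individual 6-week distance is a Gaussian baseline
  (mean 180 km over 6 weeks, i.e. 1–7 km/day) multiplied by 0.149 under
  stress — the suppression the behavioural result reports — plus noise;
  shorter windows are noisy fractions of the total with decreasing
  correlation, mimicking the reported correlation decay (0.47 down to 0.03).
* **QC violators.** Planted barcodes each violate exactly one filter rule,
  so survivor counts are arithmetic, and attribution order (min-UMI,
  min-genes, max-UMI, max-genes, mito) makes reports deterministic.
  High-gene violators require more than 5000 genes and are refused
  otherwise.

What the generator does **not** emulate: ambient RNA, doublet expression
mixtures (doublets enter only as planted count violations), batch effects
across pools, zero inflation, and gene–gene correlation beyond cluster
structure. Passing tests therefore demonstrate correctness of the methods
under the stated model, not robustness to every artefact of real droplet
data.

## Quality control

`apply_qc_filters()` keeps barcodes with at least 750 UMIs, at least 500
detected genes, at most 20,000 UMIs, at most 5000 genes, and at most 5%
mitochondrial content. The printed thresholds are exclusion bounds quoted
as strict inequalities, so a barcode at exactly 750 UMIs or exactly 5%
mito is kept. "Percent of all genes" for mitochondrial content is read as
mitochondrial UMIs over total UMIs (standard practice); the alternative
reading — detected mitochondrial genes over detected genes — is available
via `mito_denominator = "genes"` because the wording is genuinely
ambiguous. Genotype-based doublet removal is out of scope: synthetic
individual labels are trusted.

## Normalisation, embedding, graph

`normalize_residuals()` computes Pearson residuals of a Gamma-Poisson fit
per gene with a log-library offset, clipped to $\pm\sqrt{n}$. This is a
documented stand-in with the same intent as regularised NB normalisation
(variance stabilisation with library offset); bit-parity with any
particular tool is not attempted. Per-gene $\theta$ is estimated by maximum
likelihood with a method-of-moments fallback; all-zero genes yield all-zero
residual rows rather than NaN.

`pca_embed()` takes the top 3000 genes by residual variance (or all genes
if fewer) and extracts 50 components — the dimensionality the original
workflow used. Large inputs use a seeded randomised SVD with three power
iterations; the sign convention (largest-magnitude coordinate positive)
makes embeddings reproducible. Note that a randomised range finder cannot
resolve near-degenerate spectra (pure noise); for clustered data the
leading spectrum is separated and agreement with the exact SVD is
numerically tight.

`build_snn_graph()` connects nuclei by the Jaccard overlap of their 50
nearest-neighbour sets (self excluded), keeping every positive overlap
(prune = 0). `community_detect()` is Louvain multilevel refinement via
igraph at a given resolution, seeded, with labels ordered by cluster size.

## Resolution selection by the K-MST edge count

The number of subclusters is chosen nonparametrically. `build_kmst()`
builds the union of $k$ orthogonal minimum spanning trees (default
$k = 5$; the source workflow does not state $k$): compute the Euclidean
MST, remove its edges, repeat. The union has exactly $k(n-1)$ edges while
disjoint trees exist and saturates at the complete graph for large $k$.

For a candidate clustering, `within_edge_count_z()` standardises the
within-cluster edge count $R_W$ against the null of a uniform permutation
of the observed label multiset. With cluster sizes $n_k$ and falling
factorials $(n)_j$:

$$E[R_W] = m\,\frac{\sum_k (n_k)_2}{(n)_2},$$

and the second moment decomposes over ordered edge pairs that are
identical, share one endpoint, or are disjoint, with same-cluster
probabilities $\sum_k (n_k)_2/(n)_2$, $\sum_k (n_k)_3/(n)_3$ and
$[\sum_k (n_k)_4 + \sum_{k\ne l}(n_k)_2(n_l)_2]/(n)_4$. These closed forms
are verified in the tests against exhaustive enumeration for $n \le 8$ and
against 20,000 Monte-Carlo permutations on a 200-node K-MST.
`select_resolution()` scans a resolution grid, excludes degenerate
labelings (one cluster, or all singletons), and returns the
Z-maximising resolution, breaking exact ties toward fewer clusters.

Two caveats, found empirically and worth knowing:

* When clusters carry genuine continuous substructure (for example the
  maturity gradient), finer partitions that split along that substructure
  can score higher — the statistic is answering the question asked
  ("are these communities separated?"), and recovery experiments
  therefore plant discrete clusters without the gradient.
* The K-MST is built in the PCA embedding (Euclidean), matching the
  "similarity graph" description; an SNN-edge variant was considered and
  not adopted.

The recovery experiments use 3000 nuclei, 800 genes, markers at log2 fold
1.5, and a grid of 0.1–1.0 in steps of 0.1 — sizes chosen so a replicate
completes in well under a minute while leaving the planted structure
non-trivial to find.

## Maturity score

`maturity_score()` is a transcriptional-diversity score, not a
re-implementation of any published binary: (1) count detected genes per
nucleus; (2) correlate each gene's log-normalised expression with that
count; (3) average the top 200 correlated genes; (4) optionally smooth
over kNN in PC space (off by default — the analyses use only ordinal
comparisons); (5) rank-normalise to [0, 1] with midranks. Higher score =
broader expression = **less** differentiated. The description this score
follows contains an internal contradiction (both ends of the scale called
"mature"); the implementation follows the principle sentence — diversity
marks immaturity — and this paragraph is the flag. Cluster contrasts use a
Gaussian linear mixed model, score ~ cluster + (1 | individual), REML via
lme4, with a warning when a cluster is confined to a single individual.

## Differential expression

The central model is a negative-binomial mixed model per gene:

$$\log \mu_{j} = \log L_j + x_j^\top\beta + b_{i(j)},\qquad
b_i \sim N(0, \sigma^2),\ y_j \sim \mathrm{NB}(\mu_j, \theta).$$

Dispersion $\theta$ is estimated once per gene by Gamma-Poisson maximum
likelihood under the fixed-effects mean model (two rounds of mean fit and
`theta.ml`), clamped to $[10^{-3}, 10^6]$, then held fixed — mirroring the
two-step practice of estimating dispersion first and fitting the mixed
model second. The mixed model itself is fit in-package by Laplace
approximation: with a single grouping factor the marginal likelihood
factorises per individual, so the inner mode-finding is a vectorised
per-individual Newton iteration and the outer optimisation (L-BFGS-B over
$\beta$ and $\log\sigma$, bounded below in $\log\sigma$) costs milliseconds
per evaluation. Agreement with `lme4::glmer` on the same model is part of
the test suite (estimates within 2%).

Inference choices that matter at 12 individuals:

* The Laplace ML fit estimates $\sigma^2$ with divisor $q$ rather than
  $q - p$; between-individual SEs are inflated by $\sqrt{q/(q-p_b)}$
  (the REML-style correction) and referred to a $t$ distribution with
  $q - p_b$ degrees of freedom, where $p_b$ is the rank of the
  individual-level design. Without this the Wald test is anti-conservative
  under pseudoreplication (empirically 0.077 instead of 0.050 at
  $\alpha = 0.05$); with it the type-I error is calibrated.
* Nucleus-level covariates keep a large-sample normal reference.
* Boundary fits ($\hat\sigma \to 0$) are refit as fixed-effects NB GLMs
  and flagged `singular`; non-convergent fits are flagged and excluded
  from the FDR denominator rather than given sentinel p-values, so totals
  stay auditable.
* Genes detected in fewer than 1% of nuclei are not tested (a logged
  default; the source workflow does not state its filter).

Storey q-values use the smoother estimate of $\pi_0$ over
$\lambda = 0.05, \dots, 0.95$ and reduce exactly to Benjamini-Hochberg
when $\pi_0 = 1$ — an identity the tests assert vector-wise. BH is used
across enrichment sets, where no specific method is named; Storey is
reserved for the DE p-values, where one is.

Power note: with 12 individuals the between-donor standard deviation
bounds the SE of a group contrast below by $\sqrt{4\sigma_u^2/12}$. At
$\sigma_u = 0.5$ — the level used to stress the type-I calibration — not
even oracle p-values reach 80% recall at $q < 0.05$ for a twofold effect;
the information is not in the data. The recall/FDR study therefore runs
the full generator (donor effects global, hence absorbed by the offset)
with 40 planted twofold genes among 400, and the calibration and coverage
studies run the gene-level simulator at $\sigma_u = 0.5$. The scaled-down
problem sizes (400–1000 genes, 12 x 200 nuclei; the source data had ~4k
microglial nuclei over the full transcriptome) are stated here as the
package's chosen study sizes.

Marker tests between nucleus sets use the Wilcoxon rank-sum with normal
approximation and tie correction; all-tie genes return p = 1.
`pseudo_mean_expression()` averages library-corrected log1p expression
within individuals — the unit of analysis for mediation. Over- and
enrichment analyses run only on user-supplied GMT files; GeneRatio is the
fraction of input genes annotated to the set (the printed definition),
hits over input size. Preranked GSEA uses the weighted running-sum
statistic (weight = |stat|), a gene-label permutation null, and
NES = ES / mean |null ES| of matching sign; the ES agrees with an
independent implementation (fgsea) to numerical precision in the tests.

## State scores and composition

M1, M2 and metabolism scores are raw-count proportions: the sum of
transcripts over the set divided by total transcripts per nucleus. The
all-genes set scores exactly 1, and the construction is invariant to
library scaling. The bundled GMT files are synthetic stand-ins whose file
names say so; real analyses should supply curated lists. Score
comparisons reuse the Gaussian LMM. Composition tests are Pearson
chi-square without continuity correction (large tables make the
correction immaterial) plus two-sided Fisher exact tests on each
subcluster-versus-rest by group-pair 2x2 table at $\alpha = 0.05$,
uncorrected — matching the per-test reporting style — with a BH option
behind a flag. The up/down goodness-of-fit statistic is the closed form
$(n_{up} - n_{down})^2/(n_{up} + n_{down})$ on 1 df, which reproduces the
published 13.5 (21 vs 3) and 65.796 (158 vs 43) exactly.

## Mediation

`mediate()` is the linear structural pair $M = \alpha_0 + aT +
\varepsilon_M$, $Y = \gamma_0 + c'T + bM + \varepsilon_Y$: ACME $= ab$,
ADE $= c'$, total $= ab + c'$ (identical to the reduced-form OLS
coefficient). Confidence intervals are percentile bootstrap over
individuals — fewer distributional assumptions than quasi-Bayesian draws,
with n_boot and seed always recorded. At $n = 24$ the percentile interval
undercovers mildly (about 0.9 observed against nominal 0.95); this is a
known small-sample property of the percentile method, accepted here
because the design decision fixed the interval type.

`screen_mediators()` runs each candidate gene in two directions: gene as
mediator of stress -> running (direction 1) and gene as consequence of
running (direction 2). Per-direction significance flags cannot by
themselves separate cause from consequence: in a linear Gaussian system
the b-path test is exactly the partial-correlation t, which is symmetric
in the two orientations. What does differ is where the direct effect
vanishes — under a full chain the ADE is null only in the correct
orientation. The screen therefore adds an exclusive classification:
a gene is assigned to the direction whose ACME interval excludes zero and
whose standardized ADE is the weaker. The planted-scenario experiment
(chain a = 1, b = 0.5, c' = 0; consequence b2 = 1; noise SDs 0.4 / 0.2 /
0.3 for mediator genes, outcome, consequence genes; 2 x 12 individuals)
was chosen so that the planted asymmetry is detectable at this sample
size, and classification recovers both classes in over 90% of cohorts.

## Known limitations

* The resolution-selection statistic prefers finer partitions when real
  continuous substructure exists; it answers separation, not "the"
  biological K.
* The NB GLMM assumes a single random intercept; crossed or nested designs
  (pools within batches) are out of scope.
* Mediation assumes sequential ignorability and linearity; no sensitivity
  analysis is provided.
* The generator's donor effects are global per nucleus, so gene-specific
  donor variability exists only in the gene-level simulator.
* All problem sizes in the test and acceptance studies are scaled down
  from the source data's ~40k nuclei; they were chosen as the package's
  own study sizes and are stated alongside each experiment.
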