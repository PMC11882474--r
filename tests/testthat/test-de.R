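make_gene_matrix <- function(genes, meta_n = NULL) {
  # stack per-gene count vectors (rows) into a counts matrix
  m <- do.call(rbind, genes)
  tiny_counts(m)
}

test_that("dispersion estimation recovers theta and respects the clamp", {
  set.seed(30)
  # Poisson gene -> theta at/near the upper clamp
  n <- 1500
  lib <- exp(rnorm(n, log(2000), 0.3))
  ypois <- rpois(n, 1e-3 * lib)
  counts <- tiny_counts(rbind(ypois, ypois * 0))
  disp <- estimate_dispersions(counts, offset = log(pmax(lib, 1)))
  expect_gt(disp$theta[1], 1e3)
  expect_true(disp$untestable[2])
  expect_false(disp$untestable[1])

  # theta = 2 recovery across seeds
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    d <- simulate_nb_gene(12, 167, beta1 = 0, individual_sd = 0, theta = 2)
    cm <- tiny_counts(matrix(d$y, 1))
    th <- estimate_dispersions(cm, offset = log(d$lib))$theta
    if (th > 1.5 && th < 2.7) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # offset invariance: scaling all libraries leaves theta unchanged
  set.seed(77)
  d <- simulate_nb_gene(6, 200, individual_sd = 0, theta = 3)
  cm <- tiny_counts(matrix(d$y, 1))
  t1 <- estimate_dispersions(cm, offset = log(d$lib))$theta
  t2 <- estimate_dispersions(cm, offset = log(2 * d$lib))$theta
  expect_equal(t1, t2, tolerance = 1e-6)
})

test_that("the Laplace NB GLMM agrees with glmer (independent route)", {
  set.seed(42)
  d <- simulate_nb_gene(12, 150, beta1 = log(2), individual_sd = 0.5,
                        theta = 2)
  X <- cbind(intercept = 1, group = d$group)
  fit <- fit_nb_glmm(d$y, X, d$individual, log(d$lib), theta = 2)
  gm <- suppressWarnings(suppressMessages(
    lme4::glmer(y ~ group + (1 | individual), data = d,
                family = MASS::negative.binomial(theta = 2),
                offset = log(d$lib))))
  sm <- summary(gm)$coefficients
  expect_equal(fit$coefficients$beta, unname(sm[, 1]), tolerance = 0.02)
  vc <- as.data.frame(lme4::VarCorr(gm))$vcov[1]
  expect_equal(fit$sigma2, vc, tolerance = 0.05)
  # raw SEs agree before the small-sample correction
  expect_equal(fit$coefficients$se[2] / sqrt(12 / 10), unname(sm[2, 2]),
               tolerance = 0.05)
})

test_that("the GLMM reduces to the NB GLM when the variance is null", {
  set.seed(9)
  d <- simulate_nb_gene(8, 100, beta1 = 0.4, individual_sd = 0, theta = 4)
  X <- cbind(intercept = 1, group = d$group)
  fit <- fit_nb_glmm(d$y, X, d$individual, log(d$lib), theta = 4)
  expect_true(fit$singular)
  glm_fit <- suppressWarnings(
    glm(d$y ~ d$group, offset = log(d$lib),
        family = MASS::negative.binomial(theta = 4)))
  expect_equal(unname(fit$coefficients$beta), unname(coef(glm_fit)),
               tolerance = 1e-6)
})

test_that("zero-variance genes are flagged untestable", {
  fit <- fit_nb_glmm(rep(0, 60), cbind(1, rep(0:1, 30)),
                     rep(1:6, each = 10), rep(0, 60), theta = 1)
  expect_true(fit$untestable)
  expect_null(fit$coefficients)
})

test_that("de_test_all is deterministic and validates its contrast", {
  d <- generate_dataset(synth_config(
    n_genes = 60, n_nuclei = 360, n_individuals_per_group = 3,
    groups = data.frame(stress = c(0, 1), wheel = c(0, 0)),
    n_clusters = 1, marker_genes_per_cluster = 0,
    maturity_gradient = FALSE, qc_violators = no_violators, seed = 19))
  t1 <- de_test_all(d$counts, d$meta, design = "stress")
  t2 <- de_test_all(d$counts, d$meta, design = "stress")
  expect_identical(t1$p, t2$p)
  expect_error(de_test_all(d$counts, d$meta, design = "stress",
                           contrast = "wheel"), "absent")
  # q never reorders genes relative to p
  ok <- !is.na(t1$q)
  expect_equal(order(t1$p[ok]), order(t1$q[ok], t1$p[ok]))
  expect_true(all(t1$q[ok] >= t1$p[ok] * 0 & t1$q[ok] <= 1))
})

test_that("the ANCOVA design recovers a planted interaction sign", {
  te <- list(interaction = data.frame(gene = 5, log2fc = 2))
  d <- generate_dataset(synth_config(
    n_genes = 40, n_nuclei = 1200, n_individuals_per_group = 6,
    groups = data.frame(stress = c(0, 1), wheel = c(1, 1)),
    n_clusters = 1, marker_genes_per_cluster = 0,
    treatment_effect_genes = te, individual_sd = 0.1,
    maturity_gradient = FALSE, qc_violators = no_violators, seed = 23))
  ds <- de_design(d$meta, "ancova")
  expect_equal(colnames(ds$X),
               c("intercept", "stress", "distance", "stress_distance"))
  expect_equal(qr(ds$X)$rank, 4)
  off <- log(Matrix::colSums(d$counts))
  th <- estimate_dispersions(d$counts[5, , drop = FALSE], ds$X, off)$theta
  fit <- fit_nb_glmm(as.numeric(d$counts[5, ]), ds$X, ds$individual, off, th)
  row <- fit$coefficients[fit$coefficients$term == "stress", ]
  expect_gt(row$beta, 0)     # interaction planted on stressed runners
})

test_that("Storey q-values behave per construction", {
  # BH identity when pi0 is forced to 1
  set.seed(4)
  for (i in 1:10) {
    p <- runif(sample(20:200, 1))^1.3
    q <- storey_qvalues(p, pi0 = 1)$q
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_equal(storey_qvalues(rep(1, 5))$q, rep(1, 5))
  one <- storey_qvalues(0.01)
  expect_equal(one$q, one$pi0 * 0.01)
  expect_error(storey_qvalues(c(0.2, 1.4)), "\\[0, 1\\]")
  # monotone nonincreasing in rank, capped at 1
  p <- runif(500)
  q <- storey_qvalues(p)$q
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("Wilcoxon markers detect shifts and saturate under ties", {
  set.seed(11)
  G <- 30
  base <- matrix(rpois(G * 200, 5), G, 200)
  shifted <- base
  shifted[1, 101:200] <- base[1, 101:200] + 6   # strong shift on gene 1
  counts <- tiny_counts(shifted)
  res <- wilcoxon_markers(counts, 1:100, 101:200)
  expect_lt(res$p[1], 0.05)
  expect_gt(mean(res$p[-1] > 0.05), 0.8)
  expect_lt(res$log2fc[1], 0)      # group A below group B on gene 1
  # all ties -> p = 1 branch
  tied <- tiny_counts(matrix(2, 3, 6))
  rt <- wilcoxon_markers(tied, 1:3, 4:6)
  expect_true(all(rt$p == 1))
})

test_that("pseudo-mean expression obeys its averaging identities", {
  set.seed(8)
  m <- tiny_counts(matrix(rpois(40 * 6, 8), 40, 6))
  # one nucleus per individual -> rows equal the corrected vectors
  pm <- pseudo_mean_expression(m, sprintf("i%d", 1:6))
  lib <- Matrix::colSums(m)
  corr <- log1p(as.matrix(Matrix::t(Matrix::t(m) / lib)) * median(lib))
  expect_equal(unname(pm["i3", ]), unname(corr[, 3]), tolerance = 1e-12)
  # splitting one individual into equal halves and averaging recovers it
  pm2 <- pseudo_mean_expression(m, c("a", "a", "a", "a", "b", "b"))
  pmx <- pseudo_mean_expression(m, c("a1", "a1", "a2", "a2", "b", "b"))
  expect_equal(unname((pmx["a1", ] + pmx["a2", ]) / 2), unname(pm2["a", ]),
               tolerance = 1e-12)
  # equal libraries: correction reduces to log1p of rescaled counts
  eq <- tiny_counts(matrix(c(4, 0, 2, 4, 0, 2), 3, 2))
  pe <- pseudo_mean_expression(eq, c("x", "x"))
  expect_equal(unname(pe["x", ]), log1p(c(4, 0, 2)), tolerance = 1e-12)
})

test_that("overlap and over-representation match the hypergeometric oracle", {
  # N = 20, |A| = 5, |B| = 4, overlap 3 -> p = 155/4845
  ov <- overlap_test(paste0("g", 1:5), paste0("g", c(1, 2, 3, 19)), 20)
  expect_equal(ov$overlap, 3)
  expect_equal(ov$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(overlap_test(c("a"), c("b"), 10)$p, 1)        # disjoint
  expect_equal(overlap_test(paste0("g", 1:6), paste0("g", 1:6), 6)$p, 1)

  o <- ora_test(paste0("g", 1:5), list(S = paste0("g", c(1, 2, 3, 19))),
                paste0("g", 1:20))
  expect_equal(o$p, 155 / 4845, tolerance = 1e-10)
  expect_equal(o$count, 3)
  expect_equal(o$gene_ratio, 3 / 5)
  # de_genes = universe -> p = 1 for every set
  o2 <- ora_test(paste0("g", 1:20),
                 list(S1 = paste0("g", 1:4), S2 = paste0("g", 5:9)),
                 paste0("g", 1:20))
  expect_true(all(o2$p == 1))
  # duplicated inputs are deduplicated
  o3 <- ora_test(rep(paste0("g", 1:5), 2),
                 list(S = paste0("g", c(1, 2, 3, 19))), paste0("g", 1:20))
  expect_equal(o3$gene_ratio, 3 / 5)
  expect_warning(ora_test("g1", list(empty = "zz"), paste0("g", 1:20)),
                 "dropped")
})

test_that("preranked GSEA scores extremes, is antisymmetric, and matches fgsea", {
  set.seed(1)
  st <- setNames(sort(rnorm(1000), decreasing = TRUE), paste0("g", 1:1000))
  top <- paste0("g", 1:20)
  gs <- gsea_preranked(st, list(top = top), n_perm = 300, seed = 2)
  expect_gt(gs$es, 0.9)
  expect_gt(gs$nes, 0)
  expect_equal(gs$direction, "activated")
  # negating the ranking negates the ES
  gs_neg <- gsea_preranked(-st, list(top = top), n_perm = 300, seed = 2)
  expect_equal(gs_neg$es, -gs$es, tolerance = 1e-12)
  expect_equal(gs_neg$direction, "suppressed")
  # random set -> null-ish p
  rnd <- sample(names(st), 30)
  gr <- gsea_preranked(st, list(rnd = rnd), n_perm = 300, seed = 3)
  expect_gt(gr$p, 0.01)
  # independent oracle for the running-sum ES
  if (requireNamespace("fgsea", quietly = TRUE)) {
    es_ref <- fgsea::calcGseaStat(unname(st),
                                  selectedStats = which(names(st) %in% top),
                                  gseaParam = 1)
    expect_equal(gs$es, es_ref, tolerance = 1e-6)
  }
})
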