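test_that("generation is byte-identical under the same seed", {
  cfg <- synth_config(n_genes = 300, n_nuclei = 200, seed = 9,
                      qc_violators = no_violators)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$meta, d2$meta)
  expect_identical(d1$truth, d2$truth)
})

test_that("infeasible configurations raise config errors", {
  expect_error(synth_config(cluster_proportions = c(0.5, 0.4)),
               "sum to 1")
  expect_error(synth_config(suppression_factor = 0), "suppression_factor")
  expect_error(synth_config(n_genes = 100, n_clusters = 4,
                            marker_genes_per_cluster = 40),
               "marker genes exceed")
  expect_error(synth_config(
    n_genes = 2000,
    qc_violators = c(low_umi = 0, low_gene = 0, high_umi = 0,
                     high_gene = 1, high_mito = 0)),
    "high-gene")
  expect_error(synth_config(n_nuclei = 5,
    qc_violators = c(low_umi = 3, low_gene = 2, high_umi = 1,
                     high_gene = 0, high_mito = 0)),
    "more QC violators")
})

test_that("degenerate config recovers the planted expression profile", {
  cfg <- synth_config(n_genes = 400, n_nuclei = 3000, n_clusters = 1,
                      marker_genes_per_cluster = 0, individual_sd = 0,
                      maturity_gradient = FALSE,
                      qc_violators = no_violators, seed = 4)
  d <- generate_dataset(cfg)
  # expected per-gene mean = mean planted library * softmax weight; compare
  # realised gene means against expectation up to NB sampling error
  lib <- d$truth$nuclei$planted_library
  emp_share <- Matrix::rowSums(d$counts) / sum(lib)
  # shares are a fixed vector; realised shares track them tightly
  expect_gt(cor(log(emp_share + 1e-8),
                log(Matrix::rowSums(d$counts) / sum(Matrix::colSums(d$counts)) + 1e-8)),
            0.999)
  # per-gene empirical means close to expectation in aggregate
  mu_hat <- Matrix::rowMeans(d$counts)
  expect_gt(cor(mu_hat, emp_share * mean(lib)), 0.99)
})

test_that("negative-binomial sampling satisfies the variance identity", {
  # theta = 5, mean 10: Var = 10 + 100/5 = 30 within Monte-Carlo error
  cfg <- synth_config(n_genes = 50, n_nuclei = 2000, n_clusters = 1,
                      marker_genes_per_cluster = 0, individual_sd = 0,
                      dispersion_range = c(5, 5), library_logsd = 0,
                      maturity_gradient = FALSE,
                      qc_violators = no_violators, seed = 12)
  d <- generate_dataset(cfg)
  mu <- Matrix::rowMeans(d$counts)
  v <- apply(as.matrix(d$counts), 1, var)
  expected <- mu + mu^2 / 5
  sel <- mu > 2          # enough signal for a stable variance estimate
  expect_gt(sum(sel), 5)
  ratio <- v[sel] / expected[sel]
  expect_true(all(ratio > 0.75 & ratio < 1.3))
})

test_that("column sums track planted library sizes", {
  d <- generate_dataset(synth_config(n_genes = 500, n_nuclei = 2000,
                                     qc_violators = no_violators, seed = 3))
  expect_gt(cor(d$truth$nuclei$planted_library,
                Matrix::colSums(d$counts)), 0.95)
})

test_that("truth-table group frequencies match the configuration exactly", {
  cfg <- synth_config(n_genes = 300, n_nuclei = 400,
                      n_individuals_per_group = 6,
                      qc_violators = no_violators, seed = 2)
  d <- generate_dataset(cfg)
  ind <- d$truth$individuals
  expect_equal(unname(table(ind$group)), rep(6L, 4), ignore_attr = TRUE)
  # every nucleus maps to a valid individual
  expect_true(all(d$meta$individual %in% ind$individual))
  expect_identical(nrow(d$truth$nuclei), ncol(d$counts))
})

test_that("planted clusters are separable in mean-profile space", {
  d <- planted_dataset(n_nuclei = 600, n_genes = 400, k = 3, log2fc = 1,
                       seed = 6)
  # the generator's own mean-profile space: per-nucleus mean normalised
  # expression of each cluster's marker panel; true labels must separate
  lib <- Matrix::colSums(d$counts)
  logn <- log1p(as.matrix(Matrix::t(Matrix::t(d$counts) / lib)) * median(lib))
  truth <- d$truth$nuclei$cluster
  mk <- d$truth$genes$marker_cluster
  proj <- sapply(sort(unique(truth)),
                 function(k) colMeans(logn[mk == k, , drop = FALSE]))
  sil <- cluster::silhouette(truth, dist(proj))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("stress suppresses running in the individual table", {
  d <- generate_dataset(synth_config(n_genes = 200, n_nuclei = 100,
                                     qc_violators = no_violators, seed = 8))
  ind <- d$truth$individuals
  run <- ind[ind$wheel == 1, ]
  expect_lt(mean(run$dist_40d[run$stress == 1]),
            0.5 * mean(run$dist_40d[run$stress == 0]))
  expect_true(all(ind$dist_40d[ind$wheel == 0] == 0))
})
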