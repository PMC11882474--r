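make_poisson_counts <- function(G = 250, n = 1200, seed = 2,
                                lib_logsd = 0.3) {
  set.seed(seed)
  rates <- exp(rnorm(G, -6, 1)); rates <- rates / sum(rates)
  lib <- round(exp(rnorm(n, log(2000), lib_logsd)))
  tiny_counts(matrix(rpois(G * n, outer(rates, lib)), G, n))
}

test_that("Pearson residuals are calibrated on Poisson data", {
  counts <- make_poisson_counts()
  r <- normalize_residuals(counts)
  det <- Matrix::rowMeans(counts > 0)
  vv <- apply(r, 2, var)
  expect_gt(mean(vv[det > 0.05]), 0.85)
  expect_lt(mean(vv[det > 0.05]), 1.15)
  expect_true(all(abs(colMeans(r)[det > 0.05]) < 0.1))
  expect_true(all(is.finite(r)))
})

test_that("all-zero genes give all-zero residual rows", {
  m <- matrix(rpois(40 * 30, 2), 40, 30)
  m[5, ] <- 0
  r <- normalize_residuals(tiny_counts(m))
  expect_true(all(r[, 5] == 0))
})

test_that("residuals are invariant to global library scaling", {
  counts <- make_poisson_counts(G = 150, n = 800, seed = 5)
  r1 <- normalize_residuals(counts)
  r2 <- normalize_residuals(counts * 2)
  expect_lt(mean(abs(r1 - r2)), 0.1)
  expect_gt(cor(as.vector(r1), as.vector(r2)), 0.99)
})

test_that("PCA embedding identifies rank and is deterministic", {
  set.seed(3)
  # rank-2 structure plus tiny jitter
  u <- matrix(rnorm(400), 200, 2)
  v <- matrix(rnorm(2 * 60), 2, 60)
  X <- u %*% v + matrix(rnorm(200 * 60, sd = 1e-4), 200, 60)
  rownames(X) <- sprintf("c%03d", 1:200); colnames(X) <- sprintf("g%02d", 1:60)
  emb <- pca_embed(X, n_components = 10, n_variable_genes = 60)
  expect_lt(sum(emb$var_share[3:10]), 1e-4)
  expect_true(all(diff(emb$var_share) <= 1e-12))
  emb2 <- pca_embed(X, n_components = 10, n_variable_genes = 60)
  expect_identical(emb$coords, emb2$coords)
  expect_error(pca_embed(X, n_components = 100), "exceeds")
  # formals default
  expect_equal(formals(pca_embed)$n_components, 50)
})

test_that("randomised and exact SVD agree on coordinates", {
  set.seed(8)
  # structured spectrum: 5 separated factors over a noise floor
  U <- matrix(rnorm(900 * 5), 900, 5)
  V <- matrix(rnorm(5 * 500), 5, 500)
  X <- U %*% diag(c(40, 30, 22, 16, 12)) %*% V / sqrt(500) +
    matrix(rnorm(900 * 500), 900, 500)
  dimnames(X) <- list(sprintf("c%03d", 1:900), sprintf("g%03d", 1:500))
  e1 <- pca_embed(X, n_components = 5, n_variable_genes = 500, exact = TRUE)
  e2 <- pca_embed(X, n_components = 5, n_variable_genes = 500, exact = FALSE)
  for (j in 1:5)
    expect_gt(abs(cor(e1$coords[, j], e2$coords[, j])), 0.99)
})

test_that("SNN weights are Jaccard overlaps with the documented defaults", {
  # E and F share the identical kNN set {A, B} at k = 2 -> weight 1
  pts <- rbind(A = c(0, 0), B = c(0, 0.1), E = c(1, 0), F = c(-1, 0),
               far1 = c(50, 50), far2 = c(-50, 50))
  g <- build_snn_graph(pts, k = 2)
  w_ef <- g$edges$weight[(g$edges$i == 3 & g$edges$j == 4)]
  expect_equal(w_ef, 1)
  expect_equal(formals(build_snn_graph)$k, 50)
  expect_equal(formals(build_snn_graph)$prune, 0)
  expect_error(build_snn_graph(pts, k = 6), "smaller")
})

test_that("well-separated blobs produce no cross-blob SNN edges", {
  set.seed(4)
  blob1 <- matrix(rnorm(100 * 2), 100, 2)
  blob2 <- matrix(rnorm(100 * 2, mean = 100), 100, 2)
  g <- build_snn_graph(rbind(blob1, blob2), k = 10)
  cross <- (g$edges$i <= 100) != (g$edges$j <= 100)
  expect_equal(sum(cross), 0)
})

test_that("community detection splits disconnected cliques and is seeded", {
  # two 6-cliques, no edges between
  cl <- function(off) t(combn(off + 1:6, 2))
  e <- rbind(cl(0), cl(6))
  graph <- structure(list(edges = data.frame(i = e[, 1], j = e[, 2],
                                             weight = 1),
                          n = 12, k = 5, mode = "snn", barcodes = NULL),
                     class = "sn_graph")
  r1 <- community_detect(graph, resolution = 0.5, seed = 7)
  expect_equal(length(unique(r1$labels)), 2)
  expect_equal(length(unique(r1$labels[1:6])), 1)
  r2 <- community_detect(graph, resolution = 0.5, seed = 7)
  expect_identical(r1$labels, r2$labels)
  # labels are dense 0..K-1, largest cluster first
  expect_setequal(unique(r1$labels), 0:1)
})

test_that("cluster count trends upward with resolution", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(200, sd = 0.5), 100, 2),
               matrix(rnorm(200, mean = 4, sd = 0.5), 100, 2),
               matrix(rnorm(200, mean = c(0, 8), sd = 0.5), 100, 2))
  g <- build_snn_graph(pts, k = 15)
  ks <- vapply(c(0.1, 0.5, 1.5, 3),
               function(r) length(unique(community_detect(g, r, seed = 1)$labels)),
               numeric(1))
  expect_lte(ks[1], ks[length(ks)])
})

test_that("marker panels call planted identities and report ties", {
  d <- planted_dataset(n_nuclei = 300, n_genes = 400, k = 2, log2fc = 3,
                       seed = 13)
  truth <- d$truth$nuclei$cluster
  markers1 <- d$truth$genes$gene[d$truth$genes$marker_cluster == 1]
  markers2 <- d$truth$genes$gene[d$truth$genes$marker_cluster == 2]
  panels <- list(microglia = markers1, macrophage = markers2)
  sc <- score_marker_panels(d$counts, truth, panels)
  expect_equal(sc$identity[sc$cluster == 1], "microglia")
  expect_equal(sc$identity[sc$cluster == 2], "macrophage")
  expect_true(all(sc$margin > 0))
  # empty intersection -> unassigned, with a warning
  expect_warning(
    sc2 <- score_marker_panels(d$counts, truth, list(alien = c("zz1", "zz2"))),
    "no genes")
  expect_true(all(sc2$identity == "unassigned"))
  # identical panels -> reported tie
  sc3 <- score_marker_panels(d$counts, truth,
                             list(p1 = markers1, p2 = markers1))
  expect_true(all(startsWith(sc3$identity, "tie:")))
})
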