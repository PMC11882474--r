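# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures.

library(Matrix)

# tiny genes x barcodes sparse matrix with dimnames
tiny_counts <- function(mat, genes = NULL, barcodes = NULL) {
  mat <- as.matrix(mat)
  rownames(mat) <- genes %||% sprintf("g%03d", seq_len(nrow(mat)))
  colnames(mat) <- barcodes %||% sprintf("bc%03d", seq_len(ncol(mat)))
  methods::as(methods::as(Matrix(mat, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjusted Rand index
ari <- function(a, b) {
  t <- table(a, b)
  s <- sum(choose(t, 2))
  ra <- sum(choose(rowSums(t), 2)); rb <- sum(choose(colSums(t), 2))
  n <- choose(sum(t), 2)
  (s - ra * rb / n) / ((ra + rb) / 2 - ra * rb / n)
}

# exhaustive permutation moments of the within-cluster edge count:
# mean/variance of R_W over all n! orderings of the label vector
enum_edge_moments <- function(edges, labels) {
  n <- length(labels)
  stopifnot(n <= 8)
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v)) {
      sub <- perms(v[-i])
      out <- rbind(out, cbind(v[i], sub))
    }
    out
  }
  P <- perms(seq_len(n))
  rw <- apply(P, 1, function(p) {
    l <- labels[p]
    sum(l[edges[, 1]] == l[edges[, 2]])
  })
  c(mean = mean(rw), var = mean(rw^2) - mean(rw)^2)
}

# no-violator helper
no_violators <- c(low_umi = 0, low_gene = 0, high_umi = 0, high_gene = 0,
                  high_mito = 0)

# small planted-cluster dataset for clustering tests
planted_dataset <- function(n_nuclei = 600, n_genes = 600, k = 3,
                            log2fc = 2, seed = 1) {
  generate_dataset(synth_config(
    n_genes = n_genes, n_nuclei = n_nuclei, n_clusters = k,
    marker_genes_per_cluster = 25, marker_log2fc = log2fc,
    maturity_gradient = FALSE, qc_violators = no_violators, seed = seed))
}

# run the clustering pipeline (residuals -> PCA -> SNN -> scan) and return
# selected labels plus the scan
run_cluster_pipeline <- function(counts, grid = seq(0.1, 1.0, 0.1),
                                 n_pcs = 50, knn = 50, k_mst = 5, seed = 1) {
  res <- normalize_residuals(counts)
  emb <- pca_embed(res, n_components = min(n_pcs, ncol(counts) - 1), seed = seed)
  g <- build_snn_graph(emb, k = knn)
  select_resolution(emb, g, grid = grid, k_mst = k_mst, seed = seed)
}
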