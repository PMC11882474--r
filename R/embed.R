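#' Principal-component embedding of normalised residuals
#'
#' Centres the residual matrix over the top variable genes (by residual
#' variance) and extracts the leading principal components. For large inputs
#' a seeded randomised SVD (Halko-type, two power iterations) is used;
#' smaller inputs fall back to an exact SVD. The sign convention fixes the
#' largest-magnitude loading of every component positive, so coordinates are
#' reproducible across runs.
#'
#' @param residuals nuclei x genes matrix from [normalize_residuals()].
#' @param n_components number of components (default 50).
#' @param n_variable_genes top genes by residual variance to retain
#'   (default 3000; capped at the gene count).
#' @param exact force exact SVD.
#' @param seed seed for the randomised range finder.
#' @return list of class `sn_embedding`: `coords` (nuclei x n_components),
#'   `var_share` (non-increasing component variance shares), `genes_used`.
#' @export
pca_embed <- function(residuals, n_components = 50, n_variable_genes = 3000,
                      exact = FALSE, seed = 1L) {
  n <- nrow(residuals); G <- ncol(residuals)
  if (n_components > min(n, G))
    stopf("n_components = %d exceeds min(nuclei, genes) = %d",
          n_components, min(n, G))
  gv <- apply(residuals, 2, var)
  keep <- order(gv, decreasing = TRUE)[seq_len(min(n_variable_genes, G))]
  X <- residuals[, keep, drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  k <- n_components

  if (exact || n * ncol(X) <= 4e5) {
    sv <- svd(X, nu = k, nv = 0)
    d <- sv$d[seq_len(k)]
    U <- sv$u
    total_var <- sum(X^2)
  } else {
    set.seed(seed)
    p <- min(ncol(X), k + 15)
    Omega <- matrix(rnorm(ncol(X) * p), ncol(X), p)
    Y <- X %*% Omega
    for (i in 1:3) {                      # power iterations sharpen spectrum
      Y <- qr.Q(qr(Y))
      Y <- X %*% crossprod(X, Y)
    }
    Q <- qr.Q(qr(Y))
    B <- crossprod(Q, X)                  # p x genes
    sb <- svd(B, nu = k, nv = 0)
    U <- Q %*% sb$u
    d <- sb$d[seq_len(k)]
    total_var <- sum(X^2)
  }
  coords <- U %*% diag(d, k, k)
  ## deterministic sign: largest |coordinate| positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(residuals)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coords = coords,
                 var_share = d^2 / total_var,
                 genes_used = colnames(residuals)[keep]),
            class = "sn_embedding")
}

## k-nearest-neighbour index matrix (rows: points; cols: neighbour ids),
## Euclidean, excluding self. Brute force on the embedding; fine at the
## scales this pipeline runs at.
knn_index <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) stopf("k = %d must be smaller than the number of nuclei %d",
                    k, n)
  D <- as.matrix(dist(coords))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, ])
    idx[i, ] <- o[o != i][seq_len(k)]
  }
  idx
}

#' Shared-nearest-neighbour graph
#'
#' Builds the kNN sets in the embedding (Euclidean, self excluded) and
#' connects two nuclei with weight equal to the Jaccard overlap of their kNN
#' sets, so two nuclei with identical neighbour sets get weight 1. Edges
#' with weight <= `prune` are dropped; the default `prune = 0` keeps every
#' positive overlap.
#'
#' @param embedding an `sn_embedding` (or a bare coordinate matrix).
#' @param k neighbourhood size (default 50).
#' @param prune Jaccard pruning threshold (default 0).
#' @return list of class `sn_graph`: `edges` (data.frame i, j, weight with
#'   i < j), `n`, `k`, `mode = "snn"`.
#' @export
build_snn_graph <- function(embedding, k = 50, prune = 0) {
  coords <- if (inherits(embedding, "sn_embedding")) embedding$coords
            else as.matrix(embedding)
  n <- nrow(coords)
  idx <- knn_index(coords, k)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k),
                            j = as.vector(idx),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)              # shared-neighbour counts
  S <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  i <- S@i + 1L; j <- S@j + 1L; shared <- S@x
  up <- i < j
  i <- i[up]; j <- j[up]; shared <- shared[up]
  jac <- shared / (2 * k - shared)
  keep <- jac > prune
  edges <- data.frame(i = i[keep], j = j[keep], weight = jac[keep])
  structure(list(edges = edges, n = n, k = k, mode = "snn",
                 barcodes = rownames(coords)),
            class = "sn_graph")
}

#' Modularity community detection at a given resolution
#'
#' Louvain multilevel community detection (with refinement) on a weighted
#' neighbour graph, at the supplied resolution. Deterministic given the
#' seed; labels are relabelled 0..K-1 by decreasing cluster size.
#'
#' @param graph an `sn_graph`.
#' @param resolution modularity resolution parameter.
#' @param seed RNG seed for the (stochastic) refinement order.
#' @return list of class `sn_clustering`: `labels` (integer, 0-based,
#'   named by barcode when available), `resolution`, `algorithm`, `seed`.
#' @export
community_detect <- function(graph, resolution = 0.2, seed = 1L) {
  if (nrow(graph$edges) == 0) stopf("empty graph: no edges to cluster")
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$i, to = graph$edges$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(graph$n)))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = graph$edges$weight,
                                resolution = resolution)
  memb <- igraph::membership(cl)
  memb <- memb[order(as.integer(names(memb)))]
  ## relabel by decreasing size, 0-based
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relab[as.character(memb)])
  if (!is.null(graph$barcodes)) names(labels) <- graph$barcodes
  structure(list(labels = labels, resolution = resolution,
                 algorithm = "louvain", seed = seed),
            class = "sn_clustering")
}
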