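#' k-minimum-spanning-tree similarity graph
#'
#' Union of the 1st..kth orthogonal minimum spanning trees on Euclidean
#' distances in the embedding: the MST is computed, its edges removed, and
#' the construction repeated k times. The trees are pairwise edge-disjoint,
#' so the union has exactly k(n-1) edges when n > k. Zero-distance
#' (duplicate) points are allowed; ties are broken by index order through
#' the deterministic Prim sweep.
#'
#' @param embedding an `sn_embedding` or a bare coordinate matrix.
#' @param k number of orthogonal spanning trees (default 5).
#' @return list of class `kmst_graph`: `edges` (2-column integer matrix,
#'   i < j), `n`, `k`, `tree` (tree index of each edge).
#' @export
build_kmst <- function(embedding, k = 5) {
  coords <- if (inherits(embedding, "sn_embedding")) embedding$coords
            else as.matrix(embedding)
  n <- nrow(coords)
  if (n <= k) stopf("need more points (%d) than trees (k = %d)", n, k)
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  edges <- matrix(0L, k * (n - 1), 2)
  tree_id <- integer(k * (n - 1))
  pos <- 0L
  for (t in seq_len(k)) {
    tree_start <- pos + 1L
    in_tree <- logical(n); in_tree[1] <- TRUE
    best <- D[1, ]; parent <- rep(1L, n)
    best[1] <- Inf
    for (step in seq_len(n - 1)) {
      u <- which.min(best)             # first index wins ties
      if (!is.finite(best[u])) {
        ## remaining graph disconnected (earlier trees used up the edges):
        ## continue as a spanning forest from the first unreached node
        u <- which(!in_tree)[1]
        in_tree[u] <- TRUE
        best[u] <- Inf
        du <- D[u, ]
        upd <- !in_tree & du < best
        if (any(upd)) { best[upd] <- du[upd]; parent[upd] <- u }
        next
      }
      pos <- pos + 1L
      e <- sort(c(parent[u], u))
      edges[pos, ] <- e
      tree_id[pos] <- t
      in_tree[u] <- TRUE
      best[u] <- Inf
      du <- D[u, ]
      upd <- !in_tree & du < best
      if (any(upd)) { best[upd] <- du[upd]; parent[upd] <- u }
    }
    if (pos >= tree_start) {
      used <- edges[tree_start:pos, , drop = FALSE]
      D[used] <- Inf
      D[used[, c(2, 1), drop = FALSE]] <- Inf
    }
  }
  edges <- edges[seq_len(pos), , drop = FALSE]
  tree_id <- tree_id[seq_len(pos)]
  structure(list(edges = edges, n = n, k = k, tree = tree_id),
            class = "kmst_graph")
}

#' Standardized within-cluster edge count
#'
#' Scores how well a clustering separates a similarity graph: `R_W` is the
#' number of edges whose endpoints share a cluster label, standardized
#' against the null of a uniform permutation of the observed label multiset
#' (cluster sizes held fixed). The null mean and variance are exact:
#' with cluster sizes n_k and falling factorials (n)_j,
#' `E[R_W] = m * sum_k (n_k)_2 / (n)_2`, and the second moment decomposes
#' over ordered edge pairs that are identical, share one endpoint, or are
#' disjoint, with same-cluster probabilities `sum_k (n_k)_2 / (n)_2`,
#' `sum_k (n_k)_3 / (n)_3` and `[sum_k (n_k)_4 + sum_{k != l} (n_k)_2
#' (n_l)_2] / (n)_4`. Well-separated clusterings give large positive Z.
#'
#' @param graph a `kmst_graph` (or any list with an `edges` 2-column matrix
#'   and node count `n`).
#' @param labels cluster label per node (length `graph$n`).
#' @return list of class `edge_count_z`: `R_W`, `E_RW`, `Var_RW`, `Z`,
#'   `degenerate`.
#' @export
within_edge_count_z <- function(graph, labels) {
  edges <- graph$edges
  n <- graph$n
  if (length(labels) != n) stopf("labels must cover all %d graph nodes", n)
  labels <- as.integer(factor(labels))
  m <- nrow(edges)
  R_W <- sum(labels[edges[, 1]] == labels[edges[, 2]])

  nk <- tabulate(labels)
  ff <- function(x, j) {
    out <- rep(1, length(x))
    for (i in seq_len(j)) out <- out * (x - i + 1)
    pmax(out, 0)
  }
  f2 <- sum(ff(nk, 2)); f3 <- sum(ff(nk, 3)); f4 <- sum(ff(nk, 4))
  N2 <- n * (n - 1); N3 <- N2 * (n - 2); N4 <- N3 * (n - 3)
  p_same <- f2 / N2
  E_RW <- m * p_same

  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  share <- sum(deg * (deg - 1))               # ordered pairs sharing a node
  disj <- m * (m - 1) - share                 # ordered disjoint pairs
  p_share <- if (n >= 3) f3 / N3 else 0
  p_disj <- if (n >= 4) (f4 + f2^2 - sum(ff(nk, 2)^2)) / N4 else 0
  second <- m * p_same + share * p_share + disj * p_disj
  Var_RW <- max(second - E_RW^2, 0)

  degenerate <- Var_RW <= 1e-12
  Z <- if (degenerate) 0 else (R_W - E_RW) / sqrt(Var_RW)
  structure(list(R_W = R_W, E_RW = E_RW, Var_RW = Var_RW, Z = Z,
                 degenerate = degenerate),
            class = "edge_count_z")
}

#' Select the clustering resolution by the K-MST edge-count statistic
#'
#' Runs community detection over a resolution grid, scores every labelling
#' with [within_edge_count_z()] on the K-MST of the embedding, and returns
#' the resolution maximising Z. Degenerate entries (single cluster or
#' all-singletons) are excluded from the argmax; exact Z ties break toward
#' fewer clusters.
#'
#' @param embedding an `sn_embedding`.
#' @param graph an `sn_graph` from [build_snn_graph()].
#' @param grid resolutions to scan (default 0.05..2 step 0.05).
#' @param k_mst trees in the K-MST (default 5).
#' @param seed community-detection seed.
#' @param kmst optional precomputed `kmst_graph`.
#' @return list of class `resolution_scan`: `scan` (data.frame resolution,
#'   n_clusters, R_W, E_RW, Var_RW, Z, degenerate), `selected_resolution`,
#'   `selected_labels`, `k_mst`, `seed`.
#' @export
select_resolution <- function(embedding, graph,
                              grid = seq(0.05, 2, by = 0.05),
                              k_mst = 5, seed = 1L, kmst = NULL) {
  if (!length(grid)) stopf("resolution grid is empty")
  kmst <- kmst %||% build_kmst(embedding, k = k_mst)
  rows <- vector("list", length(grid))
  labelsets <- vector("list", length(grid))
  for (ii in seq_along(grid)) {
    cl <- community_detect(graph, resolution = grid[ii], seed = seed)
    z <- within_edge_count_z(kmst, cl$labels)
    rows[[ii]] <- data.frame(resolution = grid[ii],
                             n_clusters = length(unique(cl$labels)),
                             R_W = z$R_W, E_RW = z$E_RW, Var_RW = z$Var_RW,
                             Z = z$Z, degenerate = z$degenerate)
    labelsets[[ii]] <- cl$labels
  }
  scan <- do.call(rbind, rows)
  ok <- which(!scan$degenerate)
  if (!length(ok))
    stopf("all grid entries degenerate (K = 1 or all singletons); widen the resolution grid")
  ord <- ok[order(-scan$Z[ok], scan$n_clusters[ok], scan$resolution[ok])]
  best <- ord[1]
  structure(list(scan = scan,
                 selected_resolution = scan$resolution[best],
                 selected_labels = labelsets[[best]],
                 k_mst = kmst$k, seed = seed),
            class = "resolution_scan")
}

#' Score clusters against named marker panels and call identities
#'
#' Computes, per cluster and panel, the mean library-normalised expression
#' of the panel genes, and the same mean over all nuclei; the ratio is the
#' panel's enrichment in the cluster. Each cluster is called as the panel
#' with the maximal enrichment, with the margin to the runner-up reported.
#' Panels with no genes in the matrix give `unassigned`; exact ties are
#' reported as `tie:panelA|panelB`, never silently broken.
#'
#' @param counts genes x barcodes count matrix.
#' @param labels cluster label per barcode.
#' @param panels named list of gene-id vectors (e.g. from [read_gmt()]).
#' @return data.frame: cluster, one score column per panel, identity,
#'   margin.
#' @export
score_marker_panels <- function(counts, labels, panels) {
  counts <- check_counts(counts)
  stopifnot(length(labels) == ncol(counts))
  lib <- Matrix::colSums(counts)
  norm <- Matrix::t(Matrix::t(counts) / pmax(lib, 1)) * median(lib)
  cl <- sort(unique(labels))
  scores <- matrix(NA_real_, length(cl), length(panels),
                   dimnames = list(as.character(cl), names(panels)))
  enrich <- scores
  for (p in seq_along(panels)) {
    genes <- intersect(panels[[p]], rownames(counts))
    if (!length(genes)) {
      warnf("panel '%s' has no genes in the matrix", names(panels)[p])
      next
    }
    if (length(genes) < length(panels[[p]]))
      warnf("panel '%s': scoring over %d of %d genes present",
            names(panels)[p], length(genes), length(panels[[p]]))
    pg <- Matrix::colMeans(norm[genes, , drop = FALSE])
    overall <- mean(pg)
    for (ci in seq_along(cl)) {
      v <- mean(pg[labels == cl[ci]])
      scores[ci, p] <- v
      enrich[ci, p] <- if (overall > 0) v / overall else NA_real_
    }
  }
  identity <- character(length(cl)); margin <- numeric(length(cl))
  for (ci in seq_along(cl)) {
    e <- enrich[ci, ]
    if (all(is.na(e))) { identity[ci] <- "unassigned"; margin[ci] <- NA; next }
    top <- max(e, na.rm = TRUE)
    winners <- names(panels)[which(e == top)]
    if (length(winners) > 1) {
      identity[ci] <- paste0("tie:", paste(winners, collapse = "|"))
      margin[ci] <- 0
    } else {
      identity[ci] <- winners
      rest <- e[names(panels) != winners]
      margin[ci] <- if (all(is.na(rest))) NA_real_
                    else top - max(rest, na.rm = TRUE)
    }
  }
  out <- data.frame(cluster = cl)
  for (p in names(panels)) out[[p]] <- scores[, p]
  out$identity <- identity
  out$margin <- margin
  out
}
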