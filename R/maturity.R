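#' Transcriptional-diversity maturity score
#'
#' Assigns each nucleus a score in [0, 1] reflecting its transcriptional
#' diversity, on the principle that less differentiated (immature) cells
#' express a broader set of genes. Pipeline: (1) count detected genes per
#' nucleus; (2) correlate every gene's log-normalised expression with that
#' count; (3) take the top `n_signature_genes` most-correlated genes as the
#' diversity signature; (4) raw score = mean log-normalised signature
#' expression; (5) optional kNN smoothing in PC space; (6) rank-normalise
#' (midranks) to [0, 1]. Higher score = broader expression = less
#' differentiated.
#'
#' Note: descriptions of this family of scores sometimes label both ends of
#' the scale "mature"; this implementation follows the diversity principle
#' (high score = high diversity = immature) throughout.
#'
#' @param counts filtered genes x barcodes count matrix.
#' @param n_signature_genes signature size (default 200; capped at the gene
#'   count with a warning).
#' @param smooth_knn neighbours for optional score smoothing (0 = off).
#' @param embedding optional `sn_embedding` used when `smooth_knn > 0`.
#' @return data.frame of class `maturity_table`: barcode, score,
#'   detected_genes, raw.
#' @export
maturity_score <- function(counts, n_signature_genes = 200, smooth_knn = 0,
                           embedding = NULL) {
  counts <- check_counts(counts)
  n <- ncol(counts); G <- nrow(counts)
  if (n_signature_genes > G) {
    warnf("n_signature_genes (%d) exceeds gene count (%d); capped",
          n_signature_genes, G)
    n_signature_genes <- G
  }
  gc_ <- detected_genes(counts)
  lib <- pmax(Matrix::colSums(counts), 1)
  norm <- Matrix::t(Matrix::t(counts) / lib) * median(lib)
  logn <- log1p(norm)
  ## gene-by-gene Pearson correlation with detected-gene count
  logn_d <- as.matrix(logn)
  cg <- suppressWarnings(apply(logn_d, 1, function(v) cor(v, gc_)))
  cg[is.na(cg)] <- -Inf
  sig <- order(cg, decreasing = TRUE)[seq_len(n_signature_genes)]
  raw <- colMeans(logn_d[sig, , drop = FALSE])
  if (all(raw == raw[1])) raw <- gc_   # fully constant signature: fall back
  if (smooth_knn > 0) {
    if (is.null(embedding)) {
      res <- normalize_residuals(counts)
      embedding <- pca_embed(res, n_components = min(20, n - 1, G - 1),
                             n_variable_genes = G)
    }
    idx <- knn_index(embedding$coords, smooth_knn)
    raw <- vapply(seq_len(n),
                  function(i) mean(raw[c(i, idx[i, ])]), numeric(1))
  }
  r <- rank(raw, ties.method = "average")
  score <- if (n > 1) (r - 1) / (n - 1) else 0.5
  structure(data.frame(barcode = colnames(counts), score = score,
                       detected_genes = gc_, raw = raw,
                       row.names = NULL),
            class = c("maturity_table", "data.frame"))
}

#' Compare maturity scores between clusters with a linear mixed model
#'
#' Fits `score ~ cluster + (1 | individual)` by REML and reports the Wald
#' effect of every non-reference cluster, accounting for repeated nuclei
#' per individual.
#'
#' @param table a `maturity_table` augmented with `cluster` and
#'   `individual` columns (or any data.frame with score/cluster/individual).
#' @param reference_cluster cluster used as the baseline level.
#' @return an `lmm_effect` data.frame, one row per non-reference cluster.
#' @export
compare_maturity <- function(table, reference_cluster) {
  stopifnot(all(c("score", "cluster", "individual") %in% names(table)))
  dat <- data.frame(value = table$score,
                    cluster = factor(table$cluster),
                    individual = table$individual)
  lmm_effect(dat, "cluster", reference = reference_cluster)
}
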