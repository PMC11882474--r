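#' Barcode-level quality-control thresholds
#'
#' Default values follow the snRNA-seq preprocessing this pipeline
#' re-implements: barcodes with extremely few RNA molecules (< 750) or genes
#' (< 500) are treated as likely dead/dying nuclei, barcodes with extremely
#' many molecules (> 20,000) or genes (> 5000) as likely multiplets, and
#' barcodes with > 5% mitochondrial content as damaged. Exclusion is by
#' strict inequality: a barcode at exactly 750 UMIs or exactly 5% mito is
#' kept.
#'
#' @param min_umi,min_genes lower bounds (kept if >=).
#' @param max_umi,max_genes upper bounds (kept if <=).
#' @param max_mito_frac mitochondrial fraction bound (kept if <=).
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umi = 750, min_genes = 500,
                          max_umi = 20000, max_genes = 5000,
                          max_mito_frac = 0.05) {
  if (min_umi >= max_umi) stopf("min_umi must be < max_umi")
  if (min_genes >= max_genes) stopf("min_genes must be < max_genes")
  if (max_mito_frac <= 0 || max_mito_frac >= 1)
    stopf("max_mito_frac must lie in (0, 1)")
  structure(list(min_umi = min_umi, min_genes = min_genes,
                 max_umi = max_umi, max_genes = max_genes,
                 max_mito_frac = max_mito_frac),
            class = "qc_thresholds")
}

#' Apply barcode-level quality filters
#'
#' Removes barcodes violating any threshold in `thresholds`, attributing each
#' removal to the first violated rule in the fixed order (min_umi, min_genes,
#' max_umi, max_genes, mito) so the report is deterministic. The gene set is
#' never changed.
#'
#' Mitochondrial content is computed as mitochondrial UMIs over total UMIs
#' per barcode by default (the standard reading); `mito_denominator =
#' "genes"` switches to the alternative reading, detected mitochondrial
#' genes over detected genes.
#'
#' @param counts sparse genes x barcodes count matrix with dimnames.
#' @param thresholds a [qc_thresholds()] object.
#' @param mito_gene_ids character vector of mitochondrial gene ids (subset of
#'   rownames); defaults to genes matching `mito_prefix`.
#' @param mito_prefix prefix used when `mito_gene_ids` is NULL.
#' @param mito_denominator `"umi"` (default) or `"genes"`.
#' @return list with `counts` (filtered matrix) and `report`, a
#'   `qc_report` list: n_input, n_kept, n_removed_by_rule (named vector),
#'   kept_barcodes, all_removed flag.
#' @export
apply_qc_filters <- function(counts, thresholds = qc_thresholds(),
                             mito_gene_ids = NULL, mito_prefix = "Mt-",
                             mito_denominator = c("umi", "genes")) {
  if (ncol(counts) == 0) stopf("empty matrix: no barcodes to filter")
  counts <- check_counts(counts)
  mito_denominator <- match.arg(mito_denominator)
  if (is.null(mito_gene_ids))
    mito_gene_ids <- grep(paste0("^", mito_prefix), rownames(counts),
                          value = TRUE)
  if (!all(mito_gene_ids %in% rownames(counts)))
    stopf("mito_gene_ids contains genes absent from the matrix")

  umi <- Matrix::colSums(counts)
  ngene <- detected_genes(counts)
  mito <- counts[rownames(counts) %in% mito_gene_ids, , drop = FALSE]
  mito_frac <- if (mito_denominator == "umi") {
    ifelse(umi > 0, Matrix::colSums(mito) / umi, 0)
  } else {
    ifelse(ngene > 0, detected_genes(mito) / ngene, 0)
  }

  rules <- cbind(min_umi = umi < thresholds$min_umi,
                 min_genes = ngene < thresholds$min_genes,
                 max_umi = umi > thresholds$max_umi,
                 max_genes = ngene > thresholds$max_genes,
                 mito = mito_frac > thresholds$max_mito_frac)
  first_rule <- apply(rules, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else 0L
  })
  kept <- first_rule == 0L
  removed <- vapply(seq_len(ncol(rules)),
                    function(j) sum(first_rule == j), integer(1))
  names(removed) <- colnames(rules)
  report <- structure(list(
    n_input = ncol(counts), n_kept = sum(kept),
    n_removed_by_rule = removed,
    kept_barcodes = colnames(counts)[kept],
    all_removed = !any(kept)), class = "qc_report")
  if (report$all_removed)
    warnf("all %d barcodes removed by QC filters", ncol(counts))
  list(counts = counts[, kept, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC filter report: %d of %d barcodes kept\n",
              x$n_kept, x$n_input))
  cat("removed by rule (first-violated attribution):\n")
  print(x$n_removed_by_rule)
  invisible(x)
}
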