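#' Per-nucleus gene-set state scores (M1 / M2 / metabolism)
#'
#' For each supplied gene set the score of a nucleus is the sum of raw
#' transcript counts over the set divided by the nucleus's total transcript
#' count — a dimensionless proportion in [0, 1] that is invariant to
#' library-size scaling, with the all-genes set scoring exactly 1. Sets are
#' scored over their intersection with the gene universe; the coverage
#' fraction is recorded.
#'
#' @param counts genes x barcodes count matrix.
#' @param sets named list of gene sets (e.g. M1, M2, metabolism GMT).
#' @return data.frame of class `state_score_table`: barcode plus one score
#'   column per set; attribute `coverage` gives per-set fraction of genes
#'   found.
#' @export
state_scores <- function(counts, sets) {
  counts <- check_counts(counts)
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  tot <- Matrix::colSums(counts)
  out <- data.frame(barcode = colnames(counts), stringsAsFactors = FALSE)
  coverage <- numeric(length(sets)); names(coverage) <- names(sets)
  for (nm in names(sets)) {
    genes <- intersect(unique(sets[[nm]]), rownames(counts))
    if (!length(genes))
      stopf("gene set '%s' has no genes in the matrix", nm)
    coverage[nm] <- length(genes) / length(unique(sets[[nm]]))
    if (coverage[nm] < 1)
      warnf("set '%s': scoring over %.0f%% of its genes", nm,
            100 * coverage[nm])
    out[[nm]] <- as.numeric(
      Matrix::colSums(counts[genes, , drop = FALSE]) / pmax(tot, 1))
  }
  attr(out, "coverage") <- coverage
  class(out) <- c("state_score_table", class(out))
  out
}

#' Mixed-model comparison of state scores
#'
#' Fits a Gaussian linear mixed model, score ~ fixed + (1 | individual),
#' for each requested score column, sharing machinery with
#' [compare_maturity()].
#'
#' @param scores a `state_score_table` (or data.frame) augmented with
#'   `individual` and the fixed-effect column.
#' @param score_cols score columns to model.
#' @param fixed fixed-effect column name (e.g. "subcluster" or "group").
#' @param reference optional reference level.
#' @return data.frame: one `lmm_effect` block per score, with a `score`
#'   column prepended.
#' @export
score_lmm <- function(scores, score_cols, fixed, reference = NULL) {
  stopifnot(all(score_cols %in% names(scores)),
            fixed %in% names(scores), "individual" %in% names(scores))
  out <- lapply(score_cols, function(sc) {
    dat <- data.frame(value = scores[[sc]],
                      individual = scores$individual)
    dat[[fixed]] <- scores[[fixed]]
    eff <- lmm_effect(dat, fixed, reference = reference)
    cbind(score = sc, eff)
  })
  do.call(rbind, out)
}

#' Subcluster-composition tests across treatment groups
#'
#' Pearson chi-square (no continuity correction) on the full subcluster x
#' group contingency table, followed by two-sided Fisher exact tests on
#' every (subcluster vs rest) x (group pair) 2x2 table, flagged at alpha.
#' Pairwise tests are uncorrected by default, with an optional BH
#' adjustment.
#'
#' @param labels subcluster label per nucleus.
#' @param groups group label per nucleus.
#' @param alpha per-test significance threshold (default 0.05).
#' @param adjust "none" (default) or "BH" across the pairwise tests.
#' @return list of class `composition_tests`: `table`, `chisq`, `df`, `p`,
#'   `pairwise` (data.frame subcluster, group_a, group_b, odds_ratio, p,
#'   p_adj, significant).
#' @export
composition_tests <- function(labels, groups, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(labels) == length(groups))
  tab <- table(subcluster = labels, group = groups)
  if (any(dim(tab) < 2)) {
    chis <- list(statistic = 0, parameter = 0, p.value = 1)
  } else {
    chis <- suppressWarnings(chisq.test(tab, correct = FALSE))
  }
  subs <- rownames(tab); grps <- colnames(tab)
  pairs <- if (length(grps) >= 2) utils::combn(grps, 2, simplify = FALSE)
           else list()
  rows <- list()
  for (s in subs) for (pr in pairs) {
    in_s <- labels == s
    a <- groups == pr[1]; b <- groups == pr[2]
    m <- matrix(c(sum(in_s & a), sum(!in_s & a),
                  sum(in_s & b), sum(!in_s & b)), 2, 2)
    ft <- fisher.test(m)
    rows[[length(rows) + 1]] <-
      data.frame(subcluster = s, group_a = pr[1], group_b = pr[2],
                 odds_ratio = unname(ft$estimate), p = ft$p.value,
                 stringsAsFactors = FALSE)
  }
  pw <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(pw)) {
    pw$p_adj <- if (adjust == "BH") p.adjust(pw$p, "BH") else pw$p
    pw$significant <- pw$p_adj < alpha
  }
  structure(list(table = tab,
                 chisq = unname(chis$statistic),
                 df = unname(chis$parameter),
                 p = chis$p.value, pairwise = pw, alpha = alpha),
            class = "composition_tests")
}

#' Goodness-of-fit test for up- versus down-regulated gene counts
#'
#' One-degree-of-freedom chi-square against a 50:50 split:
#' `chisq = (n_up - n_down)^2 / (n_up + n_down)`, upper-tail p.
#'
#' @param n_up,n_down counts of up- and down-regulated genes.
#' @return list of class `gof_result`: n_up, n_down, chisq, df, p.
#' @export
updown_gof <- function(n_up, n_down) {
  if (n_up + n_down == 0) stopf("no genes: n_up + n_down = 0")
  chisq <- (n_up - n_down)^2 / (n_up + n_down)
  structure(list(n_up = n_up, n_down = n_down, chisq = chisq, df = 1,
                 p = pchisq(chisq, df = 1, lower.tail = FALSE)),
            class = "gof_result")
}
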