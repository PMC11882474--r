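#' Build a fixed-effects design matrix for differential expression
#'
#' Maps the study's analysis modes onto design matrices over the barcode
#' metadata: `stress` and `wheel` are single-factor contrasts, `2x2` is the
#' full stress + wheel + stress:wheel factorial, `ancova` is stress +
#' standardised running distance + their interaction (run on wheel-access
#' animals), and `distance` is a single standardised running-distance
#' covariate (one window at a time). Distances are per-individual values
#' broadcast to nuclei.
#'
#' @param meta barcode metadata with columns individual, stress, wheel and
#'   the distance windows.
#' @param design one of "stress", "wheel", "2x2", "ancova", "distance".
#' @param distance_window metadata column used by distance/ancova designs.
#' @return list: `X` (design matrix), `individual` (factor), `design`,
#'   `contrasts` (coefficient names excluding the intercept).
#' @export
de_design <- function(meta, design = c("stress", "wheel", "2x2", "ancova",
                                       "distance"),
                      distance_window = "dist_40d") {
  design <- match.arg(design)
  zdist <- function() {
    d <- meta[[distance_window]]
    if (is.null(d)) stopf("metadata lacks column %s", distance_window)
    as.numeric(scale(d))
  }
  X <- switch(design,
    stress = cbind(intercept = 1, stress = meta$stress),
    wheel = cbind(intercept = 1, wheel = meta$wheel),
    `2x2` = cbind(intercept = 1, stress = meta$stress, wheel = meta$wheel,
                  stress_wheel = meta$stress * meta$wheel),
    ancova = cbind(intercept = 1, stress = meta$stress, distance = zdist(),
                   stress_distance = meta$stress * zdist()),
    distance = cbind(intercept = 1, distance = zdist()))
  if (qr(X)$rank < ncol(X))
    stopf("design matrix is rank deficient for design '%s'", design)
  list(X = X, individual = factor(meta$individual), design = design,
       contrasts = setdiff(colnames(X), "intercept"))
}

#' Genome-wide negative-binomial mixed-model differential expression
#'
#' Runs the per-gene NB GLMM over all genes passing a detection filter:
#' dispersions are estimated once per gene by Gamma-Poisson maximum
#' likelihood ([estimate_dispersions()]), then [fit_nb_glmm()] is fit with
#' the log library offset and per-individual random intercept, and Storey
#' q-values are appended over the converged Wald p-values for the requested
#' contrast. Non-convergent genes are flagged and excluded from the FDR
#' denominator rather than assigned a sentinel p.
#'
#' @param counts genes x barcodes count matrix (post QC).
#' @param meta barcode metadata (see [de_design()]).
#' @param design analysis mode passed to [de_design()].
#' @param contrast coefficient to report (default: first non-intercept
#'   term).
#' @param detection_min minimum fraction of nuclei a gene must be detected
#'   in (default 0.01).
#' @param distance_window distance column for distance/ancova designs.
#' @param dispersions optional precomputed [estimate_dispersions()] output.
#' @return data.frame of class `de_table`: gene, beta (natural-log fold
#'   scale), se, stat, df, p, q, mean_expression, direction, converged,
#'   singular, tested. Attribute `pi0` carries the Storey null-proportion
#'   estimate; attribute `fits` the count of tested genes.
#' @export
de_test_all <- function(counts, meta, design = "stress", contrast = NULL,
                        detection_min = 0.01, distance_window = "dist_40d",
                        dispersions = NULL) {
  counts <- check_counts(counts)
  stopifnot(ncol(counts) == nrow(meta))
  ds <- de_design(meta, design, distance_window)
  if (is.null(contrast)) contrast <- ds$contrasts[1]
  if (!contrast %in% colnames(ds$X))
    stopf("contrast '%s' absent from design '%s'", contrast, design)
  offset <- log(Matrix::colSums(counts))
  det <- Matrix::rowMeans(counts > 0)
  tested <- det >= detection_min
  disp <- dispersions %||%
    estimate_dispersions(counts[tested, , drop = FALSE], ds$X, offset)
  theta_map <- setNames(disp$theta, disp$gene)

  genes <- rownames(counts)
  out <- data.frame(gene = genes, beta = NA_real_, se = NA_real_,
                    stat = NA_real_, df = NA_real_, p = NA_real_,
                    q = NA_real_,
                    mean_expression = as.numeric(Matrix::rowMeans(counts)),
                    direction = NA_character_, converged = FALSE,
                    singular = FALSE, tested = tested,
                    stringsAsFactors = FALSE)
  for (g in which(tested)) {
    th <- theta_map[[genes[g]]]
    if (is.null(th) || !is.finite(th)) { out$tested[g] <- FALSE; next }
    fit <- fit_nb_glmm(as.numeric(counts[g, ]), ds$X, ds$individual,
                       offset, th)
    if (is.null(fit$coefficients) || !fit$converged) next
    row <- fit$coefficients[fit$coefficients$term == contrast, ]
    out$beta[g] <- row$beta; out$se[g] <- row$se; out$stat[g] <- row$stat
    out$df[g] <- row$df; out$p[g] <- row$p
    out$direction[g] <- if (row$beta >= 0) "up" else "down"
    out$converged[g] <- TRUE
    out$singular[g] <- fit$singular
  }
  ok <- which(out$converged & !is.na(out$p))
  if (length(ok)) {
    qv <- storey_qvalues(out$p[ok])
    out$q[ok] <- qv$q
    attr(out, "pi0") <- qv$pi0
  }
  attr(out, "contrast") <- contrast
  attr(out, "design") <- design
  class(out) <- c("de_table", class(out))
  out
}

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion pi0 by the smoother method over a lambda
#' grid (natural cubic smoothing spline through pi0(lambda) = #\{p >
#' lambda\} / (m (1 - lambda)), evaluated at the largest lambda, capped at
#' 1), then computes q_i = min over t >= p_i of pi0 * m * t / #\{p <= t\}.
#' Forcing `pi0 = 1` reproduces Benjamini-Hochberg adjusted p-values
#' exactly.
#'
#' @param p p-values in [0, 1].
#' @param lambda grid for the pi0 smoother (default 0.05..0.95 by 0.05).
#' @param pi0 optional override of the null-proportion estimate.
#' @return list: `q` (same order as `p`), `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  if (any(p < 0 | p > 1 | is.na(p))) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 2 || max(p) < min(lambda)) {
      pi0 <- 1
    } else {
      pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- tryCatch(smooth.spline(lambda, pl, df = 3),
                      error = function(e) NULL)
      pi0 <- if (is.null(fit)) min(pl[length(pl)], 1)
             else predict(fit, x = max(lambda))$y
      pi0 <- min(pi0, 1)
      if (pi0 <= 0) {
        warnf("pi0 estimate <= 0; flooring at 1/m")
        pi0 <- 1 / m
      }
    }
  }
  o <- order(p)
  v <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(v)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m); q[o] <- q_sorted
  list(q = q, pi0 = pi0)
}

#' Wilcoxon rank-sum marker test between two nucleus sets
#'
#' Distribution-free per-gene comparison: rank-sum statistic with the
#' normal approximation and tie correction, plus a log2 fold change of
#' library-normalised means. All-tie genes get p = 1.
#'
#' @param counts genes x barcodes count matrix.
#' @param cells_a,cells_b barcode vectors (or logical/integer indices).
#' @return data.frame: gene, statistic (rank-sum W), p, log2fc, pct_a,
#'   pct_b.
#' @export
wilcoxon_markers <- function(counts, cells_a, cells_b) {
  counts <- check_counts(counts)
  A <- counts[, cells_a, drop = FALSE]
  B <- counts[, cells_b, drop = FALSE]
  lib <- Matrix::colSums(counts)
  med <- median(lib)
  An <- Matrix::t(Matrix::t(A) / Matrix::colSums(A)) * med
  Bn <- Matrix::t(Matrix::t(B) / Matrix::colSums(B)) * med
  res <- lapply(seq_len(nrow(counts)), function(g) {
    a <- as.numeric(An[g, ]); b <- as.numeric(Bn[g, ])
    if (all(c(a, b) == c(a, b)[1])) {
      w <- length(a) * length(b) / 2; pv <- 1
    } else {
      t <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                        correct = FALSE))
      w <- unname(t$statistic)
      pv <- if (is.na(t$p.value)) 1 else t$p.value
    }
    c(w, pv, log2((mean(a) + 1) / (mean(b) + 1)),
      mean(a > 0), mean(b > 0))
  })
  res <- do.call(rbind, res)
  data.frame(gene = rownames(counts), statistic = res[, 1], p = res[, 2],
             log2fc = res[, 3], pct_a = res[, 4], pct_b = res[, 5],
             stringsAsFactors = FALSE)
}

#' Per-individual mean library-corrected expression
#'
#' Averages library-corrected expression (counts / library * median
#' library, log1p) across all nuclei of each individual; the
#' individual-level matrix feeds reporting and the mediation screen.
#'
#' @param counts genes x barcodes count matrix.
#' @param individuals individual id per barcode.
#' @return individuals x genes numeric matrix.
#' @export
pseudo_mean_expression <- function(counts, individuals) {
  counts <- check_counts(counts)
  stopifnot(length(individuals) == ncol(counts))
  lib <- pmax(Matrix::colSums(counts), 1)
  logn <- log1p(Matrix::t(Matrix::t(counts) / lib) * median(lib))
  ids <- factor(individuals)
  out <- t(sapply(levels(ids), function(i)
    Matrix::rowMeans(logn[, ids == i, drop = FALSE])))
  rownames(out) <- levels(ids)
  out
}

#' Hypergeometric overlap test between two gene lists
#'
#' Upper-tail probability of seeing at least the observed overlap when
#' `|B|` genes are drawn from a universe of `universe_size` containing
#' `|A|` marked genes.
#'
#' @param list_a,list_b character vectors of gene ids (deduplicated).
#' @param universe_size size of the gene universe.
#' @return list: overlap, p.
#' @export
overlap_test <- function(list_a, list_b, universe_size) {
  a <- unique(list_a); b <- unique(list_b)
  if (length(a) > universe_size || length(b) > universe_size)
    stopf("list larger than the universe")
  ov <- length(intersect(a, b))
  p <- phyper(ov - 1, length(a), universe_size - length(a), length(b),
              lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Over-representation analysis of a DE gene list against GMT sets
#'
#' One-sided Fisher exact test per gene set against the supplied universe,
#' BH-adjusted across sets, with GeneRatio (annotated input genes / input
#' genes) and per-set hit counts. Input genes are deduplicated; sets with
#' no universe overlap are dropped with a warning.
#'
#' @param de_genes character vector of significant genes.
#' @param gmt_sets named list of gene sets (from [read_gmt()]).
#' @param universe character vector of testable genes.
#' @return data.frame: set, gene_ratio, count, p, p_adjust.
#' @export
ora_test <- function(de_genes, gmt_sets, universe) {
  universe <- unique(universe)
  de <- unique(intersect(de_genes, universe))
  rows <- lapply(names(gmt_sets), function(nm) {
    set <- intersect(unique(gmt_sets[[nm]]), universe)
    if (!length(set)) {
      warnf("set '%s' has no genes in the universe; dropped", nm)
      return(NULL)
    }
    hits <- length(intersect(de, set))
    tab <- matrix(c(hits, length(de) - hits,
                    length(set) - hits,
                    length(universe) - length(de) - length(set) + hits),
                  2, 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(set = nm, gene_ratio = hits / length(de), count = hits,
               p = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(rows)
  rows$p_adjust <- p.adjust(rows$p, method = "BH")
  rows
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score (weight =
#' absolute ranking statistic), gene-label permutation null, NES = ES
#' divided by the mean |null ES| of matching sign, empirical p-value, and
#' an activated/suppressed direction from the NES sign.
#'
#' @param ranked_stats named numeric vector of per-gene ranking statistics.
#' @param gmt_sets named list of gene sets.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return data.frame: set, size, es, nes, p, direction.
#' @export
gsea_preranked <- function(ranked_stats, gmt_sets, n_perm = 1000,
                           seed = 1L) {
  stopifnot(!is.null(names(ranked_stats)))
  ord <- order(ranked_stats, decreasing = TRUE)
  stats_o <- ranked_stats[ord]
  genes_o <- names(stats_o)
  N <- length(stats_o)
  es_of <- function(idx) {          # idx: positions in the ranked list
    hit <- logical(N); hit[idx] <- TRUE
    w <- abs(stats_o[hit])
    if (sum(w) == 0) w <- rep(1, sum(hit))
    inc <- numeric(N)
    inc[hit] <- w / sum(w)
    inc[!hit] <- -1 / (N - sum(hit))
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }
  set.seed(seed)
  rows <- lapply(names(gmt_sets), function(nm) {
    idx <- which(genes_o %in% gmt_sets[[nm]])
    sz <- length(idx)
    if (sz == 0 || sz == N) return(NULL)
    es <- es_of(idx)
    null_es <- vapply(seq_len(n_perm),
                      function(i) es_of(sample.int(N, sz)), numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else sign(es) * Inf
    p <- if (length(same)) (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
         else 1 / (n_perm + 1)
    data.frame(set = nm, size = sz, es = es, nes = nes, p = p,
               direction = if (nes > 0) "activated" else "suppressed",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
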