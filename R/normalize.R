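#' Gamma-Poisson Pearson residual normalisation
#'
#' Variance-stabilising normalisation for UMI counts: each gene is modelled
#' Gamma-Poisson with a log link, a gene intercept and the log library size
#' as offset (mu_gc = lib_c * exp(beta_g)), a per-gene overdispersion theta_g
#' is estimated by maximum likelihood on that fit, and the returned value is
#' the Pearson residual (y - mu) / sqrt(mu + mu^2 / theta), clipped to
#' +/- sqrt(n_nuclei). Genes with zero total count get all-zero residual
#' rows.
#'
#' @param counts sparse genes x barcodes count matrix; library sizes must be
#'   positive.
#' @param clip residual clipping bound; default `sqrt(ncol(counts))`.
#' @return dense nuclei x genes residual matrix (nuclei in rows so that the
#'   embedding step consumes it directly); attribute `theta` holds the
#'   per-gene dispersion estimates.
#' @export
normalize_residuals <- function(counts, clip = NULL) {
  counts <- check_counts(counts)
  lib <- Matrix::colSums(counts)
  if (any(lib <= 0)) stopf("library sizes must be positive; run QC first")
  n <- ncol(counts); G <- nrow(counts)
  clip <- clip %||% sqrt(n)
  tot <- Matrix::rowSums(counts)
  beta <- ifelse(tot > 0, log(tot / sum(lib)), -Inf)  # ML intercept w/ offset

  ## theta per gene by ML given mu (method-of-moments start, few NR steps)
  X <- Matrix::t(counts)                      # nuclei x genes
  Xd <- as.matrix(X)
  mu <- outer(lib, exp(beta))                 # nuclei x genes
  theta <- vapply(seq_len(G), function(g) {
    if (tot[g] == 0) return(Inf)
    y <- Xd[, g]; m <- mu[, g]
    v <- mean((y - m)^2 - m)
    mom <- if (v > 0) mean(m^2) / v else Inf
    if (!is.finite(mom) || mom > 1e5) return(1e5)
    est <- tryCatch(MASS::theta.ml(y, m, limit = 25),
                    error = function(e) mom, warning = function(w) mom)
    min(max(as.numeric(est), 1e-3), 1e5)
  }, numeric(1))

  denom <- sqrt(mu + sweep(mu^2, 2, theta, `/`))
  res <- (Xd - mu) / denom
  res[, tot == 0] <- 0
  res[res > clip] <- clip
  res[res < -clip] <- -clip
  dimnames(res) <- list(colnames(counts), rownames(counts))
  attr(res, "theta") <- setNames(theta, rownames(counts))
  res
}
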