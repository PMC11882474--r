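## Negative-binomial mixed model machinery.
##
## The model for one gene is
##   y_j ~ NB(mu_j, theta),  log mu_j = offset_j + x_j' beta + b_{i(j)},
##   b_i ~ N(0, sigma^2),
## with theta fixed from the Gamma-Poisson dispersion step. The marginal
## likelihood integrates the random intercepts by the Laplace approximation;
## with a single grouping factor the integral factorises per individual, so
## the inner mode-finding is a vectorised per-individual Newton iteration
## and the outer optimisation runs over (beta, log sigma).

nb_loglik_eta <- function(y, eta, theta) {
  mu <- exp(eta)
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta) + y * eta - (y + theta) * log(mu + theta))
}

## per-observation first/second derivatives of the NB loglik wrt eta
nb_deriv_eta <- function(y, eta, theta) {
  mu <- exp(eta)
  list(g = y - (y + theta) * mu / (mu + theta),
       h = -(y + theta) * theta * mu / (mu + theta)^2)
}

## inner Laplace step: mode of the joint in b given (beta, sigma2)
laplace_inner <- function(y, Xb_off, id_idx, q, sigma2, theta, b_start,
                          tol = 1e-9, maxit = 60) {
  b <- b_start
  for (it in seq_len(maxit)) {
    eta <- Xb_off + b[id_idx]
    d <- nb_deriv_eta(y, eta, theta)
    g <- rowsum(d$g, id_idx, reorder = TRUE)[, 1] - b / sigma2
    h <- rowsum(d$h, id_idx, reorder = TRUE)[, 1] - 1 / sigma2
    step <- g / h
    bnew <- b - step
    ## damp exploding steps
    bad <- abs(step) > 5
    if (any(bad)) bnew[bad] <- b[bad] - sign(step[bad]) * 5
    b <- bnew
    if (max(abs(g)) < tol) break
  }
  eta <- Xb_off + b[id_idx]
  d <- nb_deriv_eta(y, eta, theta)
  h <- rowsum(d$h, id_idx, reorder = TRUE)[, 1] - 1 / sigma2
  list(b = b, h = h, eta = eta)
}

## negative Laplace log-likelihood as a function of par = c(beta, log sigma)
make_laplace_obj <- function(y, X, offset, id_idx, q, theta) {
  env <- new.env()
  env$b <- rep(0, q)
  function(par) {
    p <- ncol(X)
    beta <- par[seq_len(p)]
    sigma2 <- exp(2 * par[p + 1])
    Xb_off <- offset + drop(X %*% beta)
    inner <- laplace_inner(y, Xb_off, id_idx, q, sigma2, theta, env$b)
    env$b <- inner$b
    ll <- nb_loglik_eta(y, inner$eta, theta) -
      sum(inner$b^2) / (2 * sigma2) -
      q / 2 * log(sigma2) - 0.5 * sum(log(-inner$h))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

#' Estimate per-gene Gamma-Poisson dispersions
#'
#' Maximum-likelihood negative-binomial size parameter per gene under a
#' fixed-effects mean model with a log-library offset (the random intercept
#' is ignored at this stage). Two rounds: a Poisson fit supplies means for a
#' first theta estimate, then the mean model is refit at that theta and
#' theta re-estimated. Estimates are clamped to [1e-3, 1e6]; all-zero genes
#' get an infinite sentinel and are flagged untestable.
#'
#' @param counts genes x barcodes count matrix.
#' @param X fixed-effects design matrix (nuclei x p), including intercept.
#' @param offset log library sizes (default from column sums).
#' @return data.frame: gene, theta, untestable, method.
#' @export
estimate_dispersions <- function(counts, X = NULL, offset = NULL) {
  counts <- check_counts(counts)
  n <- ncol(counts)
  X <- X %||% matrix(1, n, 1)
  offset <- offset %||% log(Matrix::colSums(counts))
  theta <- numeric(nrow(counts))
  untestable <- logical(nrow(counts))
  Xd <- as.matrix(X)
  for (g in seq_len(nrow(counts))) {
    y <- as.numeric(counts[g, ])
    if (sum(y) == 0) { theta[g] <- Inf; untestable[g] <- TRUE; next }
    fit <- suppressWarnings(
      stats::glm.fit(Xd, y, offset = offset, family = stats::poisson()))
    mu <- fit$fitted.values
    t1 <- suppressWarnings(tryCatch(
      as.numeric(MASS::theta.ml(y, mu, limit = 25)),
      error = function(e) NA_real_))
    if (is.na(t1) || t1 > 1e6) t1 <- 1e6
    fit2 <- suppressWarnings(tryCatch(
      stats::glm.fit(Xd, y, offset = offset,
                     family = MASS::negative.binomial(theta = t1)),
      error = function(e) fit))
    mu2 <- fit2$fitted.values
    t2 <- suppressWarnings(tryCatch(
      as.numeric(MASS::theta.ml(y, mu2, limit = 25)),
      error = function(e) t1))
    theta[g] <- min(max(t2, 1e-3), 1e6)
  }
  data.frame(gene = rownames(counts), theta = theta,
             untestable = untestable, method = "gamma_poisson_ml",
             stringsAsFactors = FALSE)
}

#' Fit the negative-binomial mixed model for one gene
#'
#' Laplace-approximation maximum likelihood for NB counts with fixed
#' dispersion, a log-library offset, fixed effects `X` and a per-individual
#' random intercept. Wald inference on each coefficient uses a t reference
#' with `df = n_individuals - rank(individual-level design)` for
#' between-individual contrasts (the honest degrees of freedom under
#' pseudoreplication) and a normal reference for nucleus-level covariates.
#' If the random-intercept variance collapses to the boundary the model is
#' refit as a fixed-effects NB GLM and flagged.
#'
#' @param y integer counts, one per nucleus.
#' @param X design matrix (nuclei x p) including the intercept.
#' @param individual factor of individual ids, one per nucleus.
#' @param offset log library sizes.
#' @param theta fixed NB size parameter.
#' @param max_iter outer iteration cap (default 200).
#' @return one-row data.frame: beta/se/df/t/p per requested coefficient is
#'   accessed via the `coefficients` element; top-level fields give the
#'   full fit: `coefficients` (data.frame term, beta, se, df, stat, p),
#'   `sigma2`, `converged`, `singular`, `loglik`.
#' @export
fit_nb_glmm <- function(y, X, individual, offset, theta, max_iter = 200) {
  individual <- droplevels(as.factor(individual))
  id_idx <- as.integer(individual)
  q <- nlevels(individual)
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (all(y == 0))
    return(list(coefficients = NULL, sigma2 = NA, converged = FALSE,
                singular = FALSE, untestable = TRUE, loglik = NA))

  ## per-level check: categorical columns need >= 2 individuals per level
  ind_design <- rowsum(X, id_idx) / as.vector(table(id_idx))
  between <- vapply(seq_len(p), function(j) {
    max(abs(X[, j] - ind_design[id_idx, j])) < 1e-12
  }, logical(1))

  start_fit <- suppressWarnings(
    stats::glm.fit(X, y, offset = offset,
                   family = MASS::negative.binomial(theta = theta)))
  beta0 <- start_fit$coefficients
  beta0[is.na(beta0)] <- 0
  obj <- make_laplace_obj(y, X, offset, id_idx, q, theta)
  par0 <- c(beta0, log(0.3))
  ## log sigma is box-constrained: the profile is flat towards -Inf when
  ## the variance component is null, so the fit lands on the lower bound
  ## and is refit as a fixed-effects GLM
  lower <- c(rep(-Inf, p), log(1e-4))
  upper <- c(rep(Inf, p), log(20))
  opt <- tryCatch(
    optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = max_iter, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(opt))
    return(list(coefficients = NULL, sigma2 = NA, converged = FALSE,
                singular = FALSE, untestable = FALSE, loglik = NA))
  converged <- opt$convergence == 0
  sigma <- unname(exp(opt$par[p + 1]))
  singular <- sigma < 2e-4

  if (singular) {
    ## boundary fit: fall back to the fixed-effects NB GLM
    fit <- suppressWarnings(
      stats::glm(y ~ 0 + X, offset = offset,
                 family = MASS::negative.binomial(theta = theta)))
    sm <- summary(fit)$coefficients
    beta <- sm[, 1]; se <- sm[, 2]
    loglik <- as.numeric(stats::logLik(fit))
  } else {
    H <- tryCatch(optimHess(opt$par, obj), error = function(e) NULL)
    if (is.null(H))
      return(list(coefficients = NULL, sigma2 = sigma^2, converged = FALSE,
                  singular = FALSE, untestable = FALSE, loglik = -opt$value))
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || any(diag(V)[seq_len(p)] <= 0))
      return(list(coefficients = NULL, sigma2 = sigma^2, converged = FALSE,
                  singular = FALSE, untestable = FALSE, loglik = -opt$value))
    beta <- opt$par[seq_len(p)]
    se <- sqrt(diag(V)[seq_len(p)])
    loglik <- -opt$value
  }

  ## REML-style small-sample correction: the Laplace ML fit estimates the
  ## random-intercept variance with divisor q rather than q - p_between,
  ## which deflates between-individual SEs by sqrt((q - p_b) / q)
  p_b <- qr(ind_design)$rank
  df_between <- max(q - p_b, 1)
  se[between] <- se[between] * sqrt(q / df_between)
  df <- ifelse(between, df_between, length(y) - p)
  stat <- beta / se
  pval <- 2 * pt(-abs(stat), df = df)
  list(coefficients = data.frame(term = colnames(X), beta = beta, se = se,
                                 df = df, stat = stat, p = pval,
                                 row.names = NULL),
       sigma2 = sigma^2, converged = converged, singular = singular,
       untestable = FALSE, loglik = loglik)
}
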