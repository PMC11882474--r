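#' Gaussian linear mixed model with an individual random intercept
#'
#' Shared machinery for score-versus-cluster/group comparisons: fits
#' `value ~ fixed + (1 | individual)` by REML via lme4 and returns one row
#' per non-reference level of the fixed factor (or per covariate), with the
#' Wald estimate, SE and normal-reference p-value, plus the random-intercept
#' and residual variances.
#'
#' @param data data.frame with columns `value`, `individual`, and the fixed
#'   term.
#' @param fixed name of the fixed-effect column (factor or numeric).
#' @param reference reference level when `fixed` is categorical.
#' @return data.frame of class `lmm_effect`: contrast, beta, se, z, p,
#'   var_individual, var_residual, singular.
#' @export
lmm_effect <- function(data, fixed, reference = NULL) {
  stopifnot(all(c("value", "individual", fixed) %in% names(data)))
  x <- data[[fixed]]
  if (!is.numeric(x)) {
    x <- factor(x)
    if (length(levels(x)) < 2)
      stopf("fixed effect '%s' has a single level; no contrast to fit", fixed)
    if (!is.null(reference)) x <- stats::relevel(x, ref = as.character(reference))
    ## warn when a level is confined to one individual (partial confounding)
    tab <- table(x, data$individual)
    lonely <- rownames(tab)[rowSums(tab > 0) == 1]
    if (length(lonely))
      warnf("level(s) %s observed in a single individual; fixed effect and random intercept are partially confounded",
            paste(lonely, collapse = ", "))
    data$..fixed <- x
  } else {
    data$..fixed <- x
  }
  fit <- suppressMessages(lme4::lmer(value ~ ..fixed + (1 | individual),
                                     data = data, REML = TRUE))
  singular <- lme4::isSingular(fit)
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_ind <- vc$vcov[vc$grp == "individual"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  rows <- grep("^\\.\\.fixed", rownames(co))
  beta <- co[rows, "Estimate"]; se <- co[rows, "Std. Error"]
  z <- beta / se
  p <- pmin(pmax(2 * pnorm(-abs(z)), .Machine$double.xmin), 1)
  out <- data.frame(contrast = sub("^\\.\\.fixed", paste0(fixed, ""),
                                   rownames(co)[rows]),
                    beta = beta, se = se, z = z, p = p,
                    var_individual = var_ind, var_residual = var_res,
                    singular = singular, row.names = NULL)
  class(out) <- c("lmm_effect", class(out))
  out
}
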