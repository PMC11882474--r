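#' @importFrom stats rnorm rlnorm runif rnbinom rmultinom rbinom rpois
#'   pnorm pt pchisq phyper fisher.test chisq.test wilcox.test
#'   dist prcomp sd var cor quantile median optim optimHess setNames
#'   coef lm vcov residuals model.matrix complete.cases p.adjust
#'   smooth.spline predict splinefun qnorm aggregate
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Column sums of detected genes per barcode
#'
#' @param counts sparse genes x barcodes count matrix.
#' @return integer vector, number of genes with count > 0 per barcode.
#' @keywords internal
detected_genes <- function(counts) {
  Matrix::colSums(counts > 0)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## counts must be a genes x barcodes dgCMatrix with dimnames
check_counts <- function(counts) {
  if (!methods::is(counts, "sparseMatrix")) {
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix needs gene rownames and barcode colnames")
  if (any(counts@x < 0)) stopf("count matrix has negative entries")
  counts
}

#' @importFrom methods is as
NULL
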