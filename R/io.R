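#' Write a count matrix in 10x-style MatrixMarket layout
#'
#' Produces `matrix.mtx` (integer coordinate, 1-based, genes x barcodes),
#' `features.tsv` and `barcodes.tsv` in `dir`, plus `metadata.tsv` when a
#' barcode metadata table is supplied.
#'
#' @param counts sparse genes x barcodes integer matrix with dimnames.
#' @param dir output directory (created if needed).
#' @param meta optional barcode metadata data.frame with a `barcode` column.
#' @return `dir`, invisibly.
#' @export
write_10x <- function(counts, dir, meta = NULL) {
  counts <- check_counts(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  feat <- data.frame(id = rownames(counts), name = rownames(counts),
                     type = "Gene Expression")
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(meta)) {
    if (!"barcode" %in% names(meta)) stopf("meta needs a barcode column")
    write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

## Validation pass over the MTX text: line-numbered diagnostics for the
## failure modes readMM reports opaquely (or not at all). The happy path is
## fully vectorised; the offending line number is recovered from the token
## index on failure.
validate_mtx <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stopf("%s: empty file", path)
  header <- lines[1]
  if (!grepl("^%%MatrixMarket +matrix +coordinate", header))
    stopf("%s line 1: malformed MatrixMarket header '%s'", path, header)
  integer_mtx <- grepl("integer", header)
  content <- which(!startsWith(lines, "%") & nzchar(trimws(lines)))
  content <- content[content > 1]
  if (!length(content)) stopf("%s: no dimension line found", path)
  badline <- function(idx, fmt, ...) {
    stopf(paste0("%s line %d: ", fmt), path, content[idx + 1L], ...)
  }
  toks <- strsplit(trimws(lines[content]), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt != 3)) {
    i <- which(nt != 3)[1]
    if (i == 1L)
      stopf("%s line %d: invalid dimension line '%s'", path, content[1],
            lines[content[1]])
    badline(i - 1L, "expected 'row col value'")
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = 3, byrow = TRUE))
  if (anyNA(vals)) {
    i <- which(rowSums(is.na(vals)) > 0)[1]
    stopf("%s line %d: non-numeric entry '%s'", path, content[i],
          lines[content[i]])
  }
  dims <- vals[1, ]
  if (any(dims < 0) || any(dims != floor(dims)))
    stopf("%s line %d: invalid dimension line '%s'", path, content[1],
          lines[content[1]])
  body <- vals[-1, , drop = FALSE]
  if (any(body[, 1] < 1 | body[, 2] < 1)) {
    i <- which(body[, 1] < 1 | body[, 2] < 1)[1]
    badline(i, "MTX indices are 1-based; got (%g, %g)",
            body[i, 1], body[i, 2])
  }
  if (any(body[, 1] > dims[1] | body[, 2] > dims[2])) {
    i <- which(body[, 1] > dims[1] | body[, 2] > dims[2])[1]
    badline(i, "index (%g, %g) exceeds declared dimensions %dx%d",
            body[i, 1], body[i, 2], dims[1], dims[2])
  }
  if (integer_mtx && any(body[, 3] != floor(body[, 3]))) {
    i <- which(body[, 3] != floor(body[, 3]))[1]
    badline(i, "non-integer entry %g in integer matrix", body[i, 3])
  }
  if (nrow(body) != dims[3])
    stopf("%s: header declares %d entries but body has %d",
          path, dims[3], nrow(body))
  dims
}

#' Read a 10x-style MatrixMarket directory
#'
#' Reads `matrix.mtx`, `features.tsv` and `barcodes.tsv` from `dir` after a
#' validation pass that reports malformed headers, 0-based indices,
#' dimension mismatches and non-integer entries with the offending line
#' number. `write_10x` followed by `read_10x` is the identity on counts and
#' identifiers (all-zero rows included).
#'
#' @param dir directory holding the three files.
#' @return list with `counts` (dgCMatrix, genes x barcodes) and `meta`
#'   (data.frame or NULL).
#' @export
read_10x <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stopf("no matrix.mtx in %s", dir)
  dims <- validate_mtx(mtx)
  m <- methods::as(methods::as(Matrix::readMM(mtx), "generalMatrix"),
                   "CsparseMatrix")
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(feats) != nrow(m))
    stopf("features.tsv has %d rows but matrix declares %d genes",
          nrow(feats), nrow(m))
  if (length(bcs) != ncol(m))
    stopf("barcodes.tsv has %d rows but matrix declares %d barcodes",
          length(bcs), ncol(m))
  dimnames(m) <- list(feats[[1]], bcs)
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- if (file.exists(meta_path))
    read.delim(meta_path, stringsAsFactors = FALSE) else NULL
  list(counts = m, meta = meta)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, tab-separated member genes).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 3)
      stopf("GMT line with fewer than 3 fields: '%s'", substr(ln, 1, 60))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln) strsplit(ln, "\t")[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
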