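test_that("default thresholds match the published filter settings", {
  thr <- qc_thresholds()
  expect_equal(thr$min_umi, 750)
  expect_equal(thr$min_genes, 500)
  expect_equal(thr$max_umi, 20000)
  expect_equal(thr$max_genes, 5000)
  expect_equal(thr$max_mito_frac, 0.05)
  expect_error(qc_thresholds(min_umi = 100, max_umi = 50), "min_umi")
})

test_that("boundary barcodes are kept (strict-inequality exclusion)", {
  # barcode 1: exactly 750 UMIs over exactly 500 non-mito genes -> kept
  # barcode 2: 749 UMIs over 499 genes -> removed, attributed to min_umi
  G <- 600
  m <- matrix(0, G, 2)
  m[26:525, 1] <- 1; m[26:275, 1] <- 2      # 500 genes, 750 UMIs
  m[26:524, 2] <- 1; m[26:275, 2] <- 2      # 499 genes, 749 UMIs
  counts <- tiny_counts(m, genes = c(sprintf("Mt-g%d", 1:25),
                                     sprintf("g%03d", 26:G)))
  stopifnot(sum(m[, 1]) == 750, sum(m[, 2] > 0) == 499)
  res <- apply_qc_filters(counts)
  expect_true("bc001" %in% res$report$kept_barcodes)
  expect_false("bc002" %in% res$report$kept_barcodes)
  expect_equal(unname(res$report$n_removed_by_rule["min_umi"]), 1)
})

test_that("mito fraction at exactly 5% is kept, just above is removed", {
  G <- 600
  base <- c(rep(0, 25), rep(1, 50), rep(2, 450), rep(0, G - 525))
  stopifnot(sum(base) == 950, sum(base > 0) == 500)
  mk <- function(mito_total) { v <- base; v[1] <- mito_total; v }
  counts <- tiny_counts(cbind(mk(50), mk(80)),   # 50/1000 = 5% exactly
                        genes = c(sprintf("Mt-g%d", 1:25),
                                  sprintf("g%03d", 26:G)))
  frac <- Matrix::colSums(counts[1:25, ]) / Matrix::colSums(counts)
  expect_equal(unname(frac[1]), 0.05)
  res <- apply_qc_filters(counts)
  expect_equal(res$report$n_kept, 1L)
  expect_true("bc001" %in% res$report$kept_barcodes)
  expect_equal(unname(res$report$n_removed_by_rule["mito"]), 1)
})

test_that("planted violators are removed with exact first-rule attribution", {
  d <- generate_dataset(qc_fixture_config(seed = 21))
  res <- apply_qc_filters(d$counts)
  expect_equal(res$report$n_kept, 89L)
  expect_equal(unname(res$report$n_removed_by_rule),
               c(5L, 3L, 2L, 0L, 1L))
  expect_equal(res$report$n_input,
               res$report$n_kept + sum(res$report$n_removed_by_rule))
  # independent per-barcode recount
  umi <- Matrix::colSums(d$counts)
  ng <- Matrix::colSums(d$counts > 0)
  mito <- Matrix::colSums(d$counts[grep("^Mt-", rownames(d$counts)), ]) / umi
  keep <- umi >= 750 & ng >= 500 & umi <= 20000 & ng <= 5000 & mito <= 0.05
  expect_setequal(res$report$kept_barcodes, colnames(d$counts)[keep])
})

test_that("filtering is idempotent and monotone in thresholds", {
  d <- generate_dataset(synth_config(n_genes = 1500, n_nuclei = 300,
                                     seed = 14,
                                     qc_violators = no_violators))
  r1 <- apply_qc_filters(d$counts)
  r2 <- apply_qc_filters(r1$counts)
  expect_equal(r2$report$n_kept, r1$report$n_kept)
  expect_equal(sum(r2$report$n_removed_by_rule), 0)
  # loosening any threshold never decreases the kept count
  loose <- apply_qc_filters(d$counts,
                            qc_thresholds(min_umi = 200, min_genes = 100,
                                          max_umi = 1e6, max_genes = 4999,
                                          max_mito_frac = 0.5))
  expect_gte(loose$report$n_kept, r1$report$n_kept)
})

test_that("degenerate inputs are handled explicitly", {
  expect_error(apply_qc_filters(tiny_counts(matrix(0, 3, 0))), "empty")
  low <- tiny_counts(matrix(1, 10, 4))   # every barcode far below min_umi
  expect_warning(res <- apply_qc_filters(low), "all 4 barcodes")
  expect_true(res$report$all_removed)
  expect_equal(ncol(res$counts), 0)
  expect_equal(nrow(res$counts), 10)     # gene set unchanged
})

test_that("both mitochondrial denominators are available", {
  m <- matrix(0, 10, 1)
  m[1, 1] <- 900      # mito gene, most UMIs
  m[2:10, 1] <- 100   # 9 genes
  counts <- tiny_counts(m, genes = c("Mt-a", sprintf("g%d", 2:10)))
  umi_frac <- 900 / 1800
  gene_frac <- 1 / 10
  expect_warning(
    r_umi <- apply_qc_filters(counts,
      qc_thresholds(min_umi = 1, min_genes = 1, max_mito_frac = 0.4)),
    "all 1 barcodes")
  expect_equal(unname(r_umi$report$n_removed_by_rule["mito"]), 1)
  r_gene <- apply_qc_filters(counts,
    qc_thresholds(min_umi = 1, min_genes = 1, max_mito_frac = 0.4),
    mito_denominator = "genes")
  expect_equal(r_gene$report$n_kept, 1L)
})
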