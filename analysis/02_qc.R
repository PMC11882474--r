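#!/usr/bin/env Rscript

# Barcode-level quality control: drop barcodes with < 750 UMIs, < 500
# detected genes, > 20,000 UMIs, > 5000 genes, or > 5% mitochondrial
# content. Writes the filtered matrix and a removal report.

suppressPackageStartupMessages({ library(striamic); library(Matrix) })

dat <- read_10x("results/data")
res <- apply_qc_filters(dat$counts, qc_thresholds())
print(res$report)

out <- "results/qc"
meta <- dat$meta[dat$meta$barcode %in% res$report$kept_barcodes, ]
write_10x(res$counts, out, meta = meta)
rep_df <- data.frame(rule = names(res$report$n_removed_by_rule),
                     removed = as.integer(res$report$n_removed_by_rule))
write.table(rep_df, file.path(out, "qc_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("kept %d of %d barcodes\n", res$report$n_kept,
            res$report$n_input))
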