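#!/usr/bin/env Rscript

# Transcriptional-diversity maturity scores per nucleus (higher = broader
# expression = less differentiated) and a linear mixed model comparing
# clusters with the individual as random intercept.

suppressPackageStartupMessages({ library(striamic); library(Matrix) })

dat <- read_10x("results/qc")
labels <- read.delim("results/cluster/labels.tsv")
out <- "results/maturity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mt <- maturity_score(dat$counts)
mt$cluster <- labels$cluster[match(mt$barcode, labels$barcode)]
mt$individual <- dat$meta$individual[match(mt$barcode, dat$meta$barcode)]
write.table(mt, file.path(out, "maturity_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ref <- names(sort(table(mt$cluster), decreasing = TRUE))[1]
eff <- compare_maturity(mt, reference_cluster = ref)
write.table(eff, file.path(out, "maturity_lmm.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("reference cluster %s; contrasts:\n", ref))
print(eff[, c("contrast", "beta", "se", "p")])
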