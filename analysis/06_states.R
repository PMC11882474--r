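#!/usr/bin/env Rscript

# M1 / M2 / metabolism state scores per nucleus (raw-count proportions),
# mixed-model comparisons across clusters, and subcluster-composition tests
# across the four treatment groups.

suppressPackageStartupMessages({ library(striamic); library(Matrix) })

dat <- read_10x("results/qc")
labels <- read.delim("results/cluster/labels.tsv")
out <- "results/states"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sets <- read_gmt(system.file("extdata", "state_sets_synthetic.gmt",
                             package = "striamic"))
sc <- state_scores(dat$counts, sets)
sc$individual <- dat$meta$individual[match(sc$barcode, dat$meta$barcode)]
sc$subcluster <- labels$cluster[match(sc$barcode, labels$barcode)]
sc$group <- paste0("s", dat$meta$stress, "w", dat$meta$wheel)[
  match(sc$barcode, dat$meta$barcode)]
write.table(sc, file.path(out, "state_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

eff <- score_lmm(sc, names(sets), fixed = "subcluster")
write.table(eff, file.path(out, "state_lmm.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(eff[, c("score", "contrast", "beta", "p")])

comp <- composition_tests(sc$subcluster, sc$group)
cat(sprintf("composition: chisq(%d) = %.2f, p = %.3g\n",
            comp$df, comp$chisq, comp$p))
write.table(as.data.frame(comp$table),
            file.path(out, "composition_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(comp$pairwise, file.path(out, "composition_pairwise.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
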