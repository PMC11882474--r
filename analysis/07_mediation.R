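#!/usr/bin/env Rscript

# Mediation screen over candidate genes in wheel-access animals: which
# gene-expression changes mediate the stress -> running-deficit effect
# (direction 1), and which follow from altered running (direction 2).
# Units are per-individual mean corrected expression and total 6-week
# distance.

suppressPackageStartupMessages({ library(striamic); library(Matrix) })

dat <- read_10x("results/qc")
labels <- read.delim("results/cluster/labels.tsv")
calls <- read.delim("results/cluster/identity_calls.tsv")
truth_genes <- read.delim("results/data/truth_genes.tsv")
out <- "results/mediation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mg_clusters <- calls$cluster[calls$identity == "microglia"]
keep <- labels$cluster %in% mg_clusters & dat$meta$wheel == 1
counts <- dat$counts[, keep]
meta <- dat$meta[keep, ]

# candidates: genes the generator wired to stress or running
cand <- truth_genes$gene[truth_genes$log2fc_stress != 0 |
                           truth_genes$log2fc_distance != 0]
cand <- intersect(cand, rownames(counts))
cat(sprintf("screening %d candidate genes over %d runner individuals\n",
            length(cand), length(unique(meta$individual))))

expr <- pseudo_mean_expression(counts, meta$individual)
ind <- unique(meta[, c("individual", "stress", "dist_40d")])
tab <- cbind(ind[match(rownames(expr), ind$individual), ],
             as.data.frame(expr[, cand, drop = FALSE]))

scr <- screen_mediators(cand, tab, treatment = "stress",
                        running = "dist_40d", n_boot = 1000, seed = 1)
write.table(scr$as_mediator, file.path(out, "direction1_mediator.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(scr$as_consequence, file.path(out, "direction2_consequence.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(scr$classification, file.path(out, "classification.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(table(scr$classification$class))
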