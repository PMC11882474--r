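#!/usr/bin/env Rscript

# Differential expression in the microglia-like cluster: NB mixed model
# (individual random intercept, log-library offset, Storey q), the up/down
# goodness-of-fit test, over-representation against the bundled gene sets,
# and preranked GSEA on the Wald statistics. The stress contrast runs on
# sedentary animals only (wheel = 0), mirroring a stress-vs-no-stress
# comparison uncontaminated by exercise.

suppressPackageStartupMessages({ library(striamic); library(Matrix) })

dat <- read_10x("results/qc")
labels <- read.delim("results/cluster/labels.tsv")
calls <- read.delim("results/cluster/identity_calls.tsv")
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mg_clusters <- calls$cluster[calls$identity == "microglia"]
if (!length(mg_clusters)) stop("no cluster called microglia")
keep <- labels$cluster %in% mg_clusters & dat$meta$wheel == 0
counts <- dat$counts[, keep]
meta <- dat$meta[keep, ]
cat(sprintf("microglia-like cluster(s) %s: %d sedentary nuclei\n",
            paste(mg_clusters, collapse = ","), ncol(counts)))

de <- de_test_all(counts, meta, design = "stress", detection_min = 0.05)
write.table(de, file.path(out, "de_stress.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sig <- de[!is.na(de$q) & de$q < 0.05, ]
n_up <- sum(sig$direction == "up"); n_down <- sum(sig$direction == "down")
cat(sprintf("%d DEGs at q < 0.05 (%d up, %d down with stress); pi0 = %.2f\n",
            nrow(sig), n_up, n_down, attr(de, "pi0")))
if (n_up + n_down > 0) {
  gof <- updown_gof(n_up, n_down)
  cat(sprintf("up/down goodness of fit: chisq(1) = %.2f, p = %.3g\n",
              gof$chisq, gof$p))
}

sets <- read_gmt(system.file("extdata", "state_sets_synthetic.gmt",
                             package = "striamic"))
universe <- de$gene[de$tested]
if (nrow(sig) > 0) {
  ora <- ora_test(sig$gene, sets, universe)
  if (!is.null(ora))
    write.table(ora, file.path(out, "ora.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
}
ranked <- setNames(de$stat[de$converged], de$gene[de$converged])
ranked <- ranked[!is.na(ranked)]
gsea <- gsea_preranked(ranked, sets, n_perm = 1000, seed = 1)
write.table(gsea, file.path(out, "gsea.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(gsea)
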