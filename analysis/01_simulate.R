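#!/usr/bin/env Rscript

# Simulate the study cohort: 4 treatment groups (stress x wheel) x 6
# individuals, ~3000 nuclei over 2000 genes, three planted cell populations
# (one "microglia-like", matching the bundled synthetic marker panels),
# treatment log-fold effects, a maturity gradient, and a handful of planted
# QC violators. Writes a 10x-style directory plus truth tables under
# results/data/.

suppressPackageStartupMessages({ library(striamic); library(Matrix) })

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# planted effects: stress mostly upregulates (21 up / 3 down, echoing the
# asymmetry the up/down test is built for); wheel access mostly
# downregulates; running distance drives a separate gene block
te <- list(
  stress = data.frame(gene = 201:224, log2fc = c(rep(1, 21), rep(-1, 3))),
  wheel = data.frame(gene = 301:330, log2fc = rep(-1, 30)),
  distance = data.frame(gene = 401:420, log2fc = rep(0.8, 20))
)

cfg <- synth_config(
  n_genes = 2000, n_nuclei = 3000, n_individuals_per_group = 6,
  n_clusters = 3, marker_genes_per_cluster = 25, marker_log2fc = 2,
  treatment_effect_genes = te,
  qc_violators = c(low_umi = 5, low_gene = 3, high_umi = 2, high_gene = 0,
                   high_mito = 2),
  seed = 20260923L)

d <- generate_dataset(cfg)
write_10x(d$counts, out, meta = d$meta)
for (nm in names(d$truth))
  write.table(d$truth[[nm]], file.path(out, paste0("truth_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes x %d nuclei, %d individuals in %d groups\n",
            nrow(d$counts), ncol(d$counts),
            nrow(d$truth$individuals), length(unique(d$meta$pool))))
cat(sprintf("planted: %d stress-, %d wheel-, %d distance-responsive genes; %d QC violators\n",
            nrow(te$stress), nrow(te$wheel), nrow(te$distance),
            sum(cfg$qc_violators)))
run <- d$truth$individuals
cat(sprintf("mean 6-week distance: %.0f km (no stress) vs %.0f km (stress)\n",
            mean(run$dist_40d[run$stress == 0 & run$wheel == 1]),
            mean(run$dist_40d[run$stress == 1 & run$wheel == 1])))
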