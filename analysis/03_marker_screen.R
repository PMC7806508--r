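#!/usr/bin/env Rscript
# The de novo marker screen: mean FPM < 1 outside ATC, fold change > 50,
# FDR <= 0.01, ranked by increasing RSD of FPM across ATC samples; the
# top 20 are annotated against the cancer-testis gene list and checked
# against the simulation's planted truth.

library(atcmarkers)

counts <- read_counts("results/sim_counts.tsv")
samples <- read_sample_sheet("results/sim_samples.tsv")
truth <- read.csv("results/sim_truth.csv", stringsAsFactors = FALSE)

scr <- run_marker_screen(counts, samples, ct_genes = ct_gene_list())
write.table(scr$markers, "results/marker_screen_top20.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

spiked <- truth$gene_id[truth$role == "spiked_marker"]
decoys <- truth$gene_id[grepl("decoy", truth$role)]
cat(sprintf("candidates passing the de novo filter: %d\n",
            length(scr$candidates)))
cat(sprintf("planted markers in the top 20: %d / 20\n",
            sum(scr$markers$gene %in% spiked)))
cat(sprintf("decoys in the top 20: %d\n",
            sum(scr$markers$gene %in% decoys)))
cat("written: results/marker_screen_top20.tsv\n")
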