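#!/usr/bin/env Rscript
# Generate the synthetic study cohort: a 2000-gene count matrix in the
# test-cohort layout (10 ATC, 6 PTC, 6 FTC, 6 NT) with 20 planted
# ATC-exclusive markers (fold change 200, low RSD) and 20 decoys, plus a
# gene-set collection containing the planted markers as a known-enriched
# set. Writes counts, sample sheet, truth table and GMT under results/.

library(atcmarkers)

dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1)
sim <- simulate_counts(cfg)

write_counts(sim$counts, "results/sim_counts.tsv")
write.table(sim$samples, "results/sim_samples.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.csv(sim$truth, "results/sim_truth.csv", row.names = FALSE)

spiked <- sim$truth$gene_id[sim$truth$role == "spiked_marker"]
sets <- make_gene_sets(rownames(sim$counts), n_sets = 10,
                       set_size_range = c(15, 50),
                       enriched_set = spiked, seed = 5)
write_gmt(sets, "results/sim_gene_sets.gmt")

cat(sprintf("cohort: %d genes x %d samples (%d spiked, %d decoys)\n",
            nrow(sim$counts), ncol(sim$counts),
            sum(sim$truth$role == "spiked_marker"),
            sum(grepl("decoy", sim$truth$role))))
cat("written: results/sim_counts.tsv, sim_samples.tsv, sim_truth.csv,",
    "sim_gene_sets.gmt\n")
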