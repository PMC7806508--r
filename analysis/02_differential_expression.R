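#!/usr/bin/env Rscript
# Differential expression of ATC against all non-ATC samples: TMM
# normalization, common-dispersion estimation, NB exact test, BH FDR, and
# a PCA embedding for cohort QC. Reads the simulated cohort from
# results/ and writes the DE table, volcano coordinates and PCA.

library(atcmarkers)

counts <- read_counts("results/sim_counts.tsv")
samples <- read_sample_sheet("results/sim_samples.tsv")
cls <- samples$class[match(colnames(counts), samples$sample_id)]
group <- factor(ifelse(cls == "ATC", "ATC", "noATC"),
                levels = c("noATC", "ATC"))

factors <- tmm_norm_factors(counts)
fpm <- compute_fpm(counts, factors)
disp <- estimate_common_dispersion(counts, group, factors)
de <- nb_exact_test(counts, group, disp, factors)

cat(sprintf("common dispersion: %.4f\n", disp$phi))
cat(sprintf("genes at FDR <= 0.01: %d of %d\n",
            sum(de$fdr <= 0.01), nrow(de)))

out <- de[, c("gene", "log2_fc", "p_value", "fdr",
              "mean_fpm_test", "mean_fpm_ref")]
names(out)[5:6] <- c("mean_fpm_atc", "mean_fpm_noatc")
write.table(out, "results/de_atc_vs_noatc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

volcano <- data.frame(gene = de$gene, log2_fc = de$log2_fc,
                      neg_log10_fdr = -log10(pmax(de$fdr, 1e-300)))
write.table(volcano, "results/volcano_coords.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

emb <- pca_embed(fpm, n_components = 2)
pca <- data.frame(sample_id = rownames(emb$coords), class = cls,
                  emb$coords)
write.table(pca, "results/pca_coords.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PC1/PC2 explained variance: %.1f%% / %.1f%%\n",
            100 * emb$explained_variance[1], 100 * emb$explained_variance[2]))
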