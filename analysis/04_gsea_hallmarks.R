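#!/usr/bin/env Rscript
# Preranked gene-set enrichment of the ATC-vs-noATC fold-change ranking
# against the simulated collection (hallmark-style): ES, NES, permutation
# p and q per set, plus the dot-plot table (NES, gene ratio, q).

library(atcmarkers)

de <- read.delim("results/de_atc_vs_noatc.tsv", stringsAsFactors = FALSE)
names(de)[names(de) == "log2FC"] <- "log2_fc"
sets <- read_gmt("results/sim_gene_sets.gmt")

ranked <- rank_by_fold_change(de)
res <- nes_and_q(ranked, sets, n_permutations = 1000, seed = 9)
write.table(res, "results/gsea_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

dot <- data.frame(set = res$set, nes = res$nes,
                  gene_ratio = lengths(strsplit(res$leading_edge, ",")) /
                    res$size,
                  q_value = res$q_value)
write.table(dot, "results/gsea_dotplot.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

top <- res[order(res$q_value), ][1, ]
cat(sprintf("most enriched set: %s (NES %.2f, q %.3g)\n",
            top$set, top$nes, top$q_value))
cat("written: results/gsea_results.tsv, gsea_dotplot.tsv\n")
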