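#!/usr/bin/env Rscript
# Step 4: per-genome COG category fractions and genus-vs-genus differential
# enrichment (two-sided exact Wilcoxon rank-sum, raw p-values).
#
# Input:  results/synthetic/annotations.tsv
# Output: results/enrichment.tsv

suppressPackageStartupMessages(library(halotribes))

genes <- read_annotations("results/synthetic/annotations.tsv")
fractions <- cog_fractions(genes)
groups <- setNames(genes$genus_id[!duplicated(genes$genome_id)],
                   genes$genome_id[!duplicated(genes$genome_id)])

tab <- enrichment_table(fractions, groups, alpha = 0.05)
tab <- tab[order(tab$p_value), ]
write.table(tab, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("categories tested: %d; significant at 0.05 (raw p): %d",
                nrow(tab), sum(tab$significant)))
trow <- tab[tab$category == "T", ]
if (nrow(trow) == 1) {
  message(sprintf(
    "signal transduction (T): %.1f%% of protein-coding genes in genusA vs %.1f%% in genusB, p = %.4g",
    100 * trow$mean_genusA, 100 * trow$mean_genusB, trow$p_value))
}
message("wrote results/enrichment.tsv")
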