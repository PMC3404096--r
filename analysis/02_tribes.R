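#!/usr/bin/env Rscript
# Step 2: build ortholog tribes within each genus from reciprocal best hits,
# join them one-to-one across genera on averaged bit scores, and assign each
# tribe its consensus function.
#
# Input:  results/synthetic/{annotations,similarity_hits}.tsv
# Output: results/tribes.tsv, results/tribe_joins.tsv

suppressPackageStartupMessages(library(halotribes))

genes <- read_annotations("results/synthetic/annotations.tsv")
hits <- read_similarity_hits("results/synthetic/similarity_hits.tsv", genes)

genus_of <- setNames(genes$genus_id, genes$gene_id)
gq <- genus_of[hits$query_id]; gs <- genus_of[hits$subject_id]

tribes_a <- build_within_genus_tribes(hits[gq == "genusA" & gs == "genusA", ],
                                      genes, "genusA")
tribes_b <- build_within_genus_tribes(hits[gq == "genusB" & gs == "genusB", ],
                                      genes, "genusB")
message(sprintf("within-genus tribes: %d (genusA), %d (genusB)",
                length(unique(tribes_a$tribe_id)),
                length(unique(tribes_b$tribe_id))))

joined <- join_tribes(tribes_a, tribes_b, hits[gq != gs, ])
joined$tribes <- tribe_functions(joined$tribes, genes)
message(sprintf("accepted cross-genus joins: %d -> %d tribes total (joined tribes counted once)",
                nrow(joined$joins), length(unique(joined$tribes$tribe_id))))

# tribes spanning every genome of both genera (the conserved core)
per_tribe_genomes <- tapply(genes$genome_id[match(joined$tribes$gene_id,
                                                  genes$gene_id)],
                            joined$tribes$tribe_id,
                            function(g) length(unique(g)))
message(sprintf("tribes present in all %d genomes: %d",
                length(unique(genes$genome_id)),
                sum(per_tribe_genomes == length(unique(genes$genome_id)))))

write_tribes(joined$tribes, "results/tribes.tsv")
write.table(joined$joins, "results/tribe_joins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/tribes.tsv, results/tribe_joins.tsv")
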