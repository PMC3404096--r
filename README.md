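# halotribes

Comparative pangenomics of two related prokaryotic genera, packaged as a
tested R pipeline. The motivating system is the haloarchaeal genera
*Haloferax* and *Haloarcula* (five and four sequenced genomes): given
all-vs-all protein similarity hits, profile-vs-proteome hits and gene
annotation tables, the package

* builds within-genus ortholog **tribes** as connected components of the
  per-genome-pair reciprocal-best-hit (RBH) graph,
* **joins tribes across genera** one-to-one by RBH on averaged bit scores
  (pair score of tribes *A*, *B* = mean bit score over all cross hits
  between their members, both directions pooled), assigning each tribe the
  modal product annotation of its members,
* filters profile hits (E-value < 10⁻⁴ and > 80% coverage of both gene and
  profile, strict), keeps each gene's best-E-value profile, and assembles a
  binary tribes × genomes **presence/absence matrix**,
* clusters the matrix on both axes (Manhattan distance, complete linkage,
  deterministic tie-breaking) and exports **Java TreeView CDT/GTR/ATR**,
* tests genus-vs-genus **COG category enrichment** with a two-sided exact
  Wilcoxon rank-sum test (complete enumeration for pooled n ≤ 12,
  mid-ranks for ties; raw p-values),
* runs targeted screens: **clade-differential tribes** (present in every
  genome of one clade, absent from every genome of another), case-
  insensitive **annotation-pattern counts** per genome superimposed on a
  species tree, a **two-domain combined-probability filter** for weak
  homologs (keep a gene when all required domains are found and the product
  of their E-values is below the per-domain threshold), and **CRISPR
  direct-repeat conservation profiles** (per-column majority fraction),
* computes **assembly summary statistics** (contigs > 200 bp, %GC,
  coverage) and group comparison numbers, including the published
  characteristics table of the two-genus study set.

A seed-reproducible **synthetic pangenome generator** with known tribe
truth (gain/loss simulated as per-branch Bernoulli toggles on a species
tree, with one clade losing genes at a boosted rate) drives validation: on
noiseless simulations the full pipeline recovers the true presence/absence
matrix exactly, and every nontrivial algorithm is checked against a
brute-force oracle. See `vignettes/halotribes-methods.Rmd` for the model,
the design decisions and their rationale.

## Worked example

```r
library(halotribes)

params <- sim_params(seed = 20120718L, n_core_tribes = 1200L,
                     n_genus_tribes = c(genusA = 400L, genusB = 400L))
truth <- generate_pangenome(params)
truth
#> synthetic pangenome: 2000 tribes, 9 genomes (genusA: 5, genusB: 4),
#>   11707 genes, 1570 gain/loss events

res <- run_tribe_pipeline(emit_annotations(truth, params),
                          emit_similarity_hits(truth, params),
                          emit_profile_hits(truth, params),
                          tribe_ids = rownames(truth$presence))
nrow(res$joined$joins)                 # accepted cross-genus joins
#> [1] 1198
tm <- truth_presence_matrix(truth)
mean(res$matrix[rownames(tm), ] == tm) # presence/absence recovery
#> [1] 1

fr <- cog_fractions(emit_annotations(truth, params))
groups <- setNames(truth$genomes$genus_id, truth$genomes$genome_id)
subset(enrichment_table(fr, groups), category == "T")
#>   category mean_genusA mean_genusB U    p_value significant
#>          T   0.0264279  0.04146333 0 0.01587302        TRUE
```

The T (signal transduction) row shows the generator's injected genus
difference (3.0% vs 4.2% expected fractions) detected at the smallest
p-value attainable for 5-vs-4 groups, 2/126 ≈ 0.0159.

The same steps, run from files with narrative output and saved tables, live
in `analysis/01_simulate.R` … `analysis/06_genome_stats.R`; each is a thin
driver over the package functions and writes under `results/`.

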