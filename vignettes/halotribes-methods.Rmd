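---
title: "Methods: ortholog tribe matrices and comparative screens for two-genus pangenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog tribe matrices and comparative screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halotribes)
```

## The pipeline

`halotribes` reconstructs a comparative-genomics workflow for two related
prokaryotic genera (the motivating system is the haloarchaeal genera
*Haloferax* and *Haloarcula*, five and four genomes respectively):

1. **Within-genus ortholog tribes.** All-vs-all protein similarity hits are
   reduced, per (query gene, subject genome) pair, to the best hit by bit
   score. A reciprocal-best-hit (RBH) edge links two genes when each is the
   other's best hit in the partner genome; tribes are the connected
   components of that graph, with edge-less genes as singletons, so every
   tribe set partitions the genus's genes.
2. **Cross-genus joining.** For every pair of tribes from the two genera,
   a pair score is the arithmetic mean of the bit scores of all cross hits
   between their members (both search directions pooled). Joins are accepted
   by RBH on pair scores — mutual best partners only — giving a one-to-one
   mapping; each joined tribe takes the modal product annotation of its
   members as consensus function.
3. **Presence/absence matrix.** Each tribe corresponds to a profile (in the
   motivating workflow, a profile HMM built from the tribe alignment).
   Profile-vs-proteome hits are filtered (E-value below `1e-4`, hit covering
   more than 80% of both the gene and the profile, both bounds strict);
   a gene hitting several profiles counts only for the one with the best
   E-value. Entry (tribe, genome) is 1 iff at least one gene of the genome
   is assigned to the tribe — binary, not a count. All-zero rows are
   retained so matrix dimensions are reproducible.
4. **Clustering and export.** Rows and columns are clustered agglomeratively
   with Manhattan distance and complete linkage, and the clustered matrix is
   exported in Java TreeView CDT/GTR/ATR format.
5. **Downstream analyses.** Genus-vs-genus COG category enrichment (exact
   Wilcoxon rank-sum test), clade-differential tribe screens, annotation
   pattern counts projected onto a species tree, a two-domain
   combined-probability homolog filter, CRISPR direct-repeat conservation
   profiles, and assembly summary statistics.

## Design decisions where the procedure was open

Several steps of the original workflow are under-specified; the package
fixes them as follows and treats each as its own design choice.

* **Tribe delineation.** The motivating workflow derived tribes from
  whole-genome alignment (positional homology) without algorithmic detail.
  This package substitutes connected components of per-genome-pair RBH
  edges: standard, deterministic, and testable. Consequences: tribes are
  defined purely by similarity, not synteny, so genuinely syntenic but
  divergent orthologs may split, and convergent high-scorers may merge.
* **Tie-breaks.** Best-hit ties are broken by lower E-value, then
  lexicographic subject id. Pair-score ties in cross-genus RBH are broken
  by higher mean hit coverage, then lexicographic tribe id. E-value ties in
  best-profile assignment are broken by higher profile coverage, then gene
  coverage, then lexicographic profile id. Modal-annotation ties take the
  lexicographically smallest label. All of these exist only to make output
  bit-reproducible; none encodes biology.
* **Self-hits** (query = subject) are dropped before any computation: they
  would inflate averaged pair scores without adding information.
* **Zero-hit tribe pairs** have undefined pair score and are never join
  candidates; nothing is imputed.
* **Joined tribes are counted once** in all tribe tallies.
* **Both search directions are pooled** when averaging cross-genus bit
  scores; the alternative (averaging per-direction averages) differs only
  when the two directions have unequal hit counts.
* **Filter boundaries are strict** ("below" / "greater than" taken
  literally): equality fails. The tests pin this behaviour at the exact
  boundary values.
* **Clade-differential rule is strict** (present in *every* in-clade
  genome, absent from *every* out-clade genome). A majority rule would be
  more tolerant of annotation noise but was not what the screen's phrasing
  describes.
* **Both axes are clustered**; scripts and callers choose which dendrograms
  to export.
* **Conservation statistic** for aligned direct repeats is the per-column
  majority-symbol fraction (bounded below by `1/n`), not pairwise percent
  identity.
* **Combined-probability threshold** for the two-domain filter equals the
  per-domain threshold (0.001): a gene with all required domains is kept if
  every per-domain E-value clears the threshold or if the product of the
  E-values does. Treating E-values as probabilities is an approximation
  (E-values are expectations, not probabilities); it is used deliberately,
  uncorrected, because reproducing the procedure is the point.

## The exact Wilcoxon rank-sum test

Category enrichment compares per-genome COG fractions between genera with
group sizes of 5 and 4 — far too small for asymptotics. `rank_sum_exact()`
computes the Mann–Whitney U with mid-ranks and, for pooled sizes up to 12,
enumerates all `choose(m+n, m)` group assignments of the pooled values,
conditioning on the observed tie pattern; the two-sided p-value is the
probability of a U at least as far from `mn/2` as observed. Beyond 12 the
normal approximation with tie correction and continuity correction is used.
The test is two-sided (the original report does not state sidedness) and no
multiple-testing correction is applied across categories, matching the
per-category reporting convention of the source analyses — callers who need
family-wise control should apply `p.adjust` downstream. Fractions use all
protein-coding genes as denominator; genes without a COG assignment stay in
the denominator, and multi-letter genes count once per letter.

At 5-vs-4 the smallest achievable two-sided p-value is `2/126 ≈ 0.0159`, so
`alpha = 0.05` is attainable and the test's discreteness keeps its true
type-I error at or below nominal (about `6/126 ≈ 0.048`).

## Clustering: why the agglomeration is implemented here

Initial Manhattan distances come from `stats::dist`. The complete-linkage
agglomeration itself is implemented in the package rather than through
`stats::hclust` because binary presence/absence matrices produce massive
distance ties, and reproducible CDT export needs a fixed, documented
tie-break: every cluster carries a creation index (leaves `1..n` in input
order, the *k*-th merged cluster `n+k`); among equally distant pairs the
lexicographically smallest index pair merges first, and the smaller-index
child becomes the left child. Complete linkage is monotone, and the
implementation asserts non-decreasing merge heights on every run. Tests
check the implementation against a naive O(n³) re-agglomeration oracle on
random binary matrices and against `stats::hclust` on tie-free data.

## The synthetic pangenome generator

No deposited assemblies are shipped; the pipeline is exercised on a
generator (`sim_params()` / `generate_pangenome()`) whose defaults emulate
the structure of the motivating study system:

* two genera with **5 and 4 genomes** on a fixed ladderized species tree
  (all branch lengths 1), user-overridable by Newick;
* **2,400 core tribes** (originating at the root) plus **1,000 tribes per
  genus** (originating at the genus ancestor), giving roughly 3,400 genes
  per genome — the observed scale of the real assemblies;
* gene **gain/loss as independent per-branch Bernoulli toggles** per tribe
  (loss 0.02, gain 0.01 per branch), with one designated three-genome clade
  of genus A losing tribes at **10×** the background rate — a deliberately
  minimal stand-in for the compound-Poisson segmental model used in the
  original gain/loss analysis, which is out of scope here. The event log is
  part of the truth object, and presence at any genome equals origin
  presence XOR the parity of toggles on the root-to-leaf path;
* **COG composition** with signal transduction (T) at 3.0% of genes in
  genus A versus 4.2% in genus B (the enrichment stage's canonical effect),
  a 67% overall COG assignment rate, and the remaining category mass spread
  evenly; per-genome fractions then fluctuate binomially, which at ~3,400
  genes gives a between-genome standard deviation near 0.003;
* **similarity scores**: within-tribe pairs at ~1.5 bits per residue with
  Gaussian noise (`score_noise_sd`, default 5 bits), spurious cross-tribe
  pairs at 20–50 bits (`noise_hit_rate` per gene, default 0.2); with zero
  noise the two score distributions are strictly separated. E-values are a
  deterministic monotone transform of bit score — only their ordering
  matters anywhere downstream;
* **profile hits**: every gene hits its own tribe's profile below `1e-8`
  E-value with >0.92 coverage; decoy hits straddle the filter thresholds on
  both sides so the filter logic is exercised in both directions. A gene's
  true hit always beats its decoys, so decoys can change best-profile
  assignment only if the true hit were absent — which cannot happen in the
  simulation.

Identical parameters (including the seed) give byte-identical output
tables; the emitters use fixed offsets from the master seed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no sequence-level evolution (hit scores are drawn,
not computed from alignments), single-copy tribes only (no paralogs, no
gene fission/fusion), no synteny (ortholog truth is assigned, not
positional), no annotation error in product strings, and E-value/score
relationships far cleaner than real search output. Exact-recovery results
on noiseless simulations validate the pipeline's bookkeeping, not its
robustness to biological mess; the noisy defaults probe ordering and
threshold behaviour, not realism.

## Numerical and degenerate-input conventions

* Hit-table coordinates are 1-based inclusive; alignment span is
  `end − start + 1`; coverage prefers annotation-table lengths over spans.
* Readers reject nothing silently: malformed rows raise errors carrying the
  line number; unknown gene ids in hit tables warn and keep the row with
  `NA` coverage.
* An empty tribe (no members) is an error; an empty filtered hit table is a
  legal empty result; a single-item clustering axis is an error; a genome
  with zero genes is an error in fraction computation.
* The discrepancy rate of a resequencing control uses the mean of the two
  assembly lengths; the median of an even-length region list is the mean of
  the middle pair.
* Contig counts use the strict `> 200 bp` convention, but assembled bp
  always sums all contigs.

## Problem sizes used by the test suite and acceptance script

The packaged validation runs at deliberately chosen scales: unit tests use
small parameterisations (40 core + 2×12 genus tribes) and hand-built
tables; oracle-equivalence tests use ≤12-item instances where brute force
is exact; the Monte-Carlo checks use 100–200 seeded replicates (clade loss
rates, COG fraction calibration, enrichment power) and 1,000 replicates for
type-I error; the end-to-end run uses 9 genomes and 2,000 tribes (1,200
core + 2×400), the scale at which the full pipeline — generation, tribes,
joining, matrix, both clusterings, CDT export, enrichment — completes in
well under five minutes on a single CPU. The published-numbers module runs
from a ten-row table and is instantaneous.

## Known limitations

* The RBH-component tribe definition is a stand-in for the original
  positional-homology procedure (see above); tribe counts on real data
  would differ.
* The product rule over E-values is statistically informal; it reproduces
  the screened procedure rather than improving it.
* The exact Wilcoxon enumeration is capped at pooled size 12 (924 splits);
  the normal fallback is adequate but not exact for moderate sizes.
* `read_similarity_hits` keeps rows referencing unknown genes (with a
  warning); downstream stages that need genome assignments will then error
  — intentional, but it means validation happens late.
* The CDT writer targets the standard Java TreeView dialect; other viewers'
  CDT variants are not handled.
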