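# Targeted gene screens over annotations, the presence/absence matrix,
# domain evidence tables, aligned CRISPR direct repeats and species trees.

#' Count genes matching annotation patterns, per genome
#'
#' A gene matches a pattern when its product string contains the pattern as a
#' case-insensitive substring (plain text, not a regular expression) — the
#' standard "search the annotation text" screen used to count, e.g.,
#' TATA-binding proteins, cellulases or CRISPR-associated genes per genome.
#'
#' @param genes annotation table (see [read_annotations()]).
#' @param patterns non-empty character vector of substring patterns.
#' @return dense `data.frame`: `genome_id` followed by one integer column per
#'   pattern (zero-count cells present).
#' @export
screen_by_annotation <- function(genes, patterns) {
  if (length(patterns) == 0) stop("patterns must be non-empty", call. = FALSE)
  if (any(!nzchar(patterns))) stop("empty pattern string", call. = FALSE)
  genomes <- unique(genes$genome_id)
  out <- data.frame(genome_id = genomes, stringsAsFactors = FALSE)
  prod_lc <- tolower(genes$product)
  for (p in patterns) {
    hit <- grepl(tolower(p), prod_lc, fixed = TRUE)
    cnt <- table(factor(genes$genome_id[hit], levels = genomes))
    out[[p]] <- as.integer(cnt)
  }
  out
}

#' Tribes present throughout one clade and absent from another
#'
#' Strict all-in / none-out rule: a tribe qualifies iff its matrix entry is 1
#' in every `clade_in` genome and 0 in every `clade_out` genome. Swapping the
#' clades yields a disjoint tribe set.
#'
#' @param mat binary presence/absence matrix (tribes x genomes).
#' @param clade_in,clade_out disjoint, non-empty genome sets (column names of
#'   `mat`).
#' @return character vector of qualifying tribe ids (matrix row order).
#' @export
clade_differential_genes <- function(mat, clade_in, clade_out) {
  if (length(clade_in) == 0 || length(clade_out) == 0)
    stop("both clades must be non-empty", call. = FALSE)
  if (length(intersect(clade_in, clade_out)) > 0)
    stop("clades overlap: ", intersect(clade_in, clade_out)[1], call. = FALSE)
  missing <- setdiff(c(clade_in, clade_out), colnames(mat))
  if (length(missing) > 0)
    stop("genome not in matrix: ", missing[1], call. = FALSE)
  all_in <- rowSums(mat[, clade_in, drop = FALSE] == 1) == length(clade_in)
  none_out <- rowSums(mat[, clade_out, drop = FALSE] == 0) == length(clade_out)
  rownames(mat)[all_in & none_out]
}

#' Multi-domain combined-probability homolog filter
#'
#' A gene is retained iff every required domain was found on it AND either
#' (a) each domain's best E-value is below `per_domain_alpha`, or (b) the
#' product of the best E-values across the required domains is below
#' `per_domain_alpha` — the rationale being that finding *all* domains by
#' chance is unlikely even when the individual matches are insignificant
#' (E-values are treated as probabilities for the product rule; a documented
#' statistical approximation, not a corrected one). A gene missing any
#' required domain is rejected outright. With `per_domain_alpha = Inf` the
#' filter retains exactly the genes carrying all required domains.
#'
#' @param evidence `data.frame` with columns `gene_id`, `domain`, `evalue`
#'   (best E-value of that domain on that gene; absent row = domain not
#'   found).
#' @param required_domains non-empty character vector of domain names.
#' @param per_domain_alpha significance threshold (default 0.001); also used
#'   as the combined-probability threshold.
#' @return character vector of retained gene ids (sorted).
#' @export
multi_domain_filter <- function(evidence, required_domains,
                                per_domain_alpha = 0.001) {
  if (length(required_domains) == 0)
    stop("required_domains must be non-empty", call. = FALSE)
  ev <- evidence[evidence$domain %in% required_domains, , drop = FALSE]
  if (nrow(ev) == 0) return(character(0))
  # best E-value per (gene, domain), in case of duplicate rows
  ord <- order(ev$gene_id, ev$domain, ev$evalue)
  ev <- ev[ord, , drop = FALSE]
  ev <- ev[!duplicated(ev[c("gene_id", "domain")]), , drop = FALSE]
  by_gene <- split(ev, ev$gene_id)
  keep <- vapply(by_gene, function(g) {
    if (!setequal(intersect(g$domain, required_domains), required_domains))
      return(FALSE)
    all(g$evalue < per_domain_alpha) ||
      prod(g$evalue) < per_domain_alpha
  }, logical(1))
  sort(names(by_gene)[keep])
}

#' Per-column conservation profile of aligned direct repeats
#'
#' For each alignment column the conservation is the frequency of the modal
#' (majority) symbol: `count(modal symbol) / n sequences`. Identical columns
#' score 1; a column with all symbols different scores `1/n`. The profile is
#' invariant to sequence order; when several symbols tie for the mode the
#' tied maximal fraction is reported and the lexicographically smallest
#' symbol is recorded (display only).
#'
#' @param aligned_repeats named character vector of >= 2 equal-length aligned
#'   sequences over the alphabet `A, C, G, T, U, -` (case-insensitive).
#' @return `data.frame` with `position`, `conservation` (in (0, 1]) and
#'   `modal_symbol`.
#' @export
dr_conservation <- function(aligned_repeats) {
  if (length(aligned_repeats) < 2)
    stop("need at least 2 aligned sequences", call. = FALSE)
  seqs <- toupper(aligned_repeats)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop(sprintf("ragged alignment: lengths %s",
                 paste(sort(unique(lens)), collapse = ", ")), call. = FALSE)
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(chars)), c("A", "C", "G", "T", "U", "-"))
  if (length(bad) > 0)
    stop("symbol outside alphabet {A,C,G,T,U,-}: ", bad[1], call. = FALSE)
  n <- nrow(chars)
  prof <- apply(chars, 2, function(col) {
    counts <- table(col)
    top <- max(counts)
    list(frac = top / n, sym = sort(names(counts)[counts == top])[1])
  })
  data.frame(position = seq_along(prof),
             conservation = vapply(prof, function(p) p$frac, numeric(1)),
             modal_symbol = vapply(prof, function(p) p$sym, character(1)),
             stringsAsFactors = FALSE)
}

#' Superimpose per-genome counts onto a species tree
#'
#' Augments each tip label with its count vector (joined with underscores, so
#' the decorated Newick re-parses to the same topology) and returns a
#' companion flat table ordered by tree tip order.
#'
#' @param tree an [ape::phylo] tree whose tips are genome ids.
#' @param counts count table from [screen_by_annotation()] (`genome_id`
#'   column plus one column per pattern).
#' @param default_missing if `TRUE`, tips absent from `counts` default to
#'   zero counts; otherwise they are an error.
#' @return list with `tree` (decorated phylo), `newick` (decorated Newick
#'   string) and `table` (counts in tip order).
#' @export
annotate_tree <- function(tree, counts, default_missing = FALSE) {
  tips <- tree$tip.label
  missing <- setdiff(tips, counts$genome_id)
  if (length(missing) > 0 && !default_missing)
    stop("tree leaf missing from counts: ", missing[1], call. = FALSE)
  patterns <- setdiff(names(counts), "genome_id")
  tab <- data.frame(genome_id = tips, stringsAsFactors = FALSE)
  idx <- match(tips, counts$genome_id)
  for (p in patterns) {
    v <- counts[[p]][idx]
    v[is.na(v)] <- 0L
    tab[[p]] <- v
  }
  decorated <- tree
  suffix <- apply(as.matrix(tab[patterns]), 1, paste, collapse = "_")
  decorated$tip.label <- paste(tips, suffix, sep = "_")
  list(tree = decorated,
       newick = ape::write.tree(decorated),
       table = tab)
}
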