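# Genus-vs-genus COG functional category enrichment.
#
# Per-genome category fractions use ALL protein-coding genes as denominator
# (genes without a COG assignment stay in the denominator); a gene carrying
# several category letters contributes to each of them, so fractions need not
# sum to one. Group differences are tested with a two-sided exact Wilcoxon
# rank-sum test: for pooled sample sizes up to 12 the null distribution of
# the Mann-Whitney U statistic is obtained by complete enumeration of all
# C(m+n, m) rank assignments, conditioning on the observed tie pattern
# (mid-ranks); larger samples fall back to the normal approximation with tie
# correction and continuity correction. Raw p-values are reported without
# multiple-testing correction, mirroring the reporting convention of the
# comparative studies this reproduces; treat marginal calls accordingly.

#' Per-genome COG category fractions
#'
#' `fraction(genome, letter)` = number of genes of that genome carrying the
#' category letter divided by the genome's total number of protein-coding
#' genes. Genes with multiple letters count once per letter; genes with no
#' letters count only in the denominator.
#'
#' @param genes annotation table (see [read_annotations()]).
#' @param categories category letters to tabulate; default: every letter
#'   observed in `genes`.
#' @return `data.frame` with `genome_id` followed by one numeric column per
#'   category.
#' @export
cog_fractions <- function(genes, categories = NULL) {
  if (nrow(genes) == 0)
    stop("genome with zero genes: empty annotation table", call. = FALSE)
  genomes <- unique(genes$genome_id)
  letters_per_gene <- strsplit(genes$cog, "", fixed = TRUE)
  if (is.null(categories)) {
    categories <- sort(unique(unlist(letters_per_gene)))
  }
  n_genes <- table(genes$genome_id)[genomes]
  out <- data.frame(genome_id = genomes, stringsAsFactors = FALSE)
  reps <- lengths(letters_per_gene)
  long_genome <- rep(genes$genome_id, reps)
  long_letter <- unlist(letters_per_gene)
  for (cat in categories) {
    cnt <- table(factor(long_genome[long_letter == cat], levels = genomes))
    out[[cat]] <- as.numeric(cnt) / as.numeric(n_genes)
  }
  out
}

#' Two-sided exact Wilcoxon rank-sum test
#'
#' Computes the Mann-Whitney U statistic for group `x` against group `y`
#' using mid-ranks for ties. For `m + n <= 12` the two-sided p-value is exact:
#' all `choose(m + n, m)` assignments of the pooled (tied) values to the
#' groups are enumerated and the p-value is the probability of a U at least
#' as far from its null mean `mn/2` as observed. Above that, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list with `U`, `p_value` and `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_exact <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group must contain at least 2 values", call. = FALSE)
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  dev_obs <- abs(U - mu)
  if (N <= 12) {
    splits <- combn(N, m)
    U_all <- colSums(matrix(r[splits], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(U_all - mu) >= dev_obs - 1e-9)
    return(list(U = U, p_value = p, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (dev_obs - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-max(z, 0)))
  list(U = U, p_value = p, method = "normal")
}

#' Genus-vs-genus enrichment table over COG categories
#'
#' One row per category present in at least one genome: the per-genus mean
#' fractions, the Mann-Whitney U statistic, the raw two-sided p-value from
#' [rank_sum_exact()], and a significance flag at `alpha`. No
#' multiple-testing correction is applied.
#'
#' @param fractions per-genome fraction table from [cog_fractions()].
#' @param groups named character vector mapping genome id to genus id
#'   (exactly two genera, each with >= 2 genomes).
#' @param alpha significance level for the flag (default 0.05).
#' @return `data.frame`: `category`, `mean_<genusA>`, `mean_<genusB>`, `U`,
#'   `p_value`, `significant`.
#' @export
enrichment_table <- function(fractions, groups, alpha = 0.05) {
  unknown <- setdiff(fractions$genome_id, names(groups))
  if (length(unknown) > 0)
    stop("genome missing from groups: ", unknown[1], call. = FALSE)
  genus <- unname(groups[fractions$genome_id])
  genera <- sort(unique(genus))
  if (length(genera) != 2)
    stop("exactly two genera required, found: ",
         paste(genera, collapse = ", "), call. = FALSE)
  if (any(table(genus) < 2))
    stop("each genus needs at least 2 genomes", call. = FALSE)
  cats <- setdiff(names(fractions), "genome_id")
  rows <- lapply(cats, function(cat) {
    v <- fractions[[cat]]
    if (all(v == 0)) return(NULL)  # category absent from every genome
    a <- v[genus == genera[1]]; b <- v[genus == genera[2]]
    ts <- rank_sum_exact(a, b)
    data.frame(category = cat, mean_a = mean(a), mean_b = mean(b),
               U = ts$U, p_value = ts$p_value,
               significant = ts$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(category = character(), mean_a = numeric(),
                      mean_b = numeric(), U = numeric(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", genera)
  rownames(out) <- NULL
  out
}
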