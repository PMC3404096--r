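# Per-assembly summary statistics and cross-group comparison numbers, plus
# the published genome characteristics of the nine Haloferax / Haloarcula
# assemblies (and the resequencing control) that the comparison figures are
# computed from.

#' Summary statistics for one genome assembly
#'
#' Contig counting uses the conventional strict `> 200 bp` display filter;
#' `assembled_bp` is always the sum of ALL contig lengths regardless of that
#' filter. Percent GC is over assembled bases; coverage is total read bases
#' over assembled bases when read data is supplied.
#'
#' @param contigs named character vector of contig sequences (e.g. from
#'   [read_fasta()]).
#' @param reads_bp optional total sequenced bases, for the coverage estimate.
#' @param cds_count,coding_bp,rna_count optional annotation-derived feature
#'   counts; `pct_coding` is computed when `coding_bp` is given.
#' @return list of class `halo_genome_stats`: `n_contigs` (> 200 bp),
#'   `n_contigs_total`, `contig_lengths`, `assembled_bp`, `gc_count`,
#'   `pct_gc`, `coverage` (or `NA`), `cds_count`, `coding_bp`, `pct_coding`,
#'   `rna_count`.
#' @export
assembly_summary <- function(contigs, reads_bp = NULL, cds_count = NULL,
                             coding_bp = NULL, rna_count = NULL) {
  if (length(contigs) == 0) stop("empty contig set", call. = FALSE)
  lens <- nchar(contigs)
  assembled <- sum(lens)
  gc <- sum(vapply(gregexpr("[GCgc]", contigs), function(m)
    if (m[1] == -1L) 0L else length(m), integer(1)))
  if (!is.null(coding_bp) && coding_bp > assembled)
    stop("coding_bp exceeds assembled_bp", call. = FALSE)
  out <- list(
    n_contigs = sum(lens > 200),
    n_contigs_total = length(lens),
    contig_lengths = unname(lens),
    assembled_bp = assembled,
    gc_count = gc,
    pct_gc = 100 * gc / assembled,
    coverage = if (is.null(reads_bp)) NA_real_ else reads_bp / assembled,
    cds_count = cds_count %||% NA_integer_,
    coding_bp = coding_bp %||% NA_integer_,
    pct_coding = if (is.null(coding_bp)) NA_real_ else
      100 * coding_bp / assembled,
    rna_count = rna_count %||% NA_integer_)
  class(out) <- "halo_genome_stats"
  out
}

#' @export
print.halo_genome_stats <- function(x, ...) {
  cat(sprintf("assembly: %d contigs > 200 bp (%d total), %s bp, %.2f%% GC",
              x$n_contigs, x$n_contigs_total,
              format(x$assembled_bp, big.mark = ","), x$pct_gc))
  if (!is.na(x$coverage)) cat(sprintf(", %.0fx coverage", x$coverage))
  cat("\n")
  invisible(x)
}

#' Between-group genome size / gene count comparison
#'
#' For genome groups `a` and `b` computes the standard "how much smaller is
#' group a" summary quartet:
#' percent size difference `(1 - mean_bp(a)/mean_bp(b)) * 100`; absolute CDS
#' difference `mean_cds(b) - mean_cds(a)`; percent CDS difference (relative
#' to group b); and contig-count ratio `mean_contigs(b)/mean_contigs(a)`.
#' Values are returned unrounded; the conventional reporting precision is one
#' decimal for percentages and the ratio, nearest integer for gene counts.
#'
#' @param stats `data.frame` with columns `genome_id`, `assembled_bp`,
#'   `cds_count`, `n_contigs` (any column may hold `NA` for genomes not used
#'   in that comparison).
#' @param group_a,group_b non-empty genome id sets.
#' @return list: `pct_size_smaller`, `cds_fewer`, `pct_cds_fewer`,
#'   `contig_ratio`.
#' @export
genus_comparison <- function(stats, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  missing <- setdiff(c(group_a, group_b), stats$genome_id)
  if (length(missing) > 0)
    stop("genome missing from stats: ", missing[1], call. = FALSE)
  pick <- function(col, ids)
    stats[[col]][match(ids, stats$genome_id)]
  mean_bp_a <- mean(pick("assembled_bp", group_a), na.rm = TRUE)
  mean_bp_b <- mean(pick("assembled_bp", group_b), na.rm = TRUE)
  mean_cds_a <- mean(pick("cds_count", group_a), na.rm = TRUE)
  mean_cds_b <- mean(pick("cds_count", group_b), na.rm = TRUE)
  mean_ctg_a <- mean(pick("n_contigs", group_a), na.rm = TRUE)
  mean_ctg_b <- mean(pick("n_contigs", group_b), na.rm = TRUE)
  list(pct_size_smaller = (1 - mean_bp_a / mean_bp_b) * 100,
       cds_fewer = mean_cds_b - mean_cds_a,
       pct_cds_fewer = (mean_cds_b - mean_cds_a) / mean_cds_b * 100,
       contig_ratio = mean_ctg_b / mean_ctg_a)
}

#' Control-vs-reference assembly discrepancy summary
#'
#' Summarises a pre-computed variant/region table from a resequencing control
#' against its published reference: the single-base discrepancy rate (one
#' differently called base per so-many Kbp, using the mean of the two
#' assembly lengths) and count/median/total summaries of the missing and
#' extra regions. Detection of the discrepancies is upstream; this operation
#' only summarises them.
#'
#' @param n_discrepancies number of single-base call discrepancies (>= 0).
#' @param assembly_lengths lengths (bp) of the two assemblies being compared.
#' @param missing_regions,extra_regions vectors of region lengths (bp).
#' @return list of class `halo_discrepancy_report`: `n_base_discrepancies`,
#'   `rate_kbp_per_discrepancy` (`NA` when there are no discrepancies) and
#'   `missing` / `extra` summaries (`count`, `median_bp`, `total_bp`; the
#'   median of an even-length list is the mean of the middle pair, and is
#'   `NA` for an empty list).
#' @export
control_discrepancy_summary <- function(n_discrepancies, assembly_lengths,
                                        missing_regions = integer(0),
                                        extra_regions = integer(0)) {
  n_discrepancies <- check_count(n_discrepancies, "n_discrepancies")
  if (any(assembly_lengths <= 0) || any(missing_regions <= 0) ||
      any(extra_regions <= 0))
    stop("lengths must be positive", call. = FALSE)
  region_summary <- function(lens) {
    list(count = length(lens),
         median_bp = if (length(lens) == 0) NA_real_ else median(lens),
         total_bp = sum(lens))
  }
  out <- list(
    n_base_discrepancies = n_discrepancies,
    rate_kbp_per_discrepancy = if (n_discrepancies == 0) NA_real_ else
      mean(assembly_lengths) / n_discrepancies / 1000,
    missing = region_summary(missing_regions),
    extra = region_summary(extra_regions))
  class(out) <- "halo_discrepancy_report"
  out
}

#' @export
print.halo_discrepancy_report <- function(x, ...) {
  rate <- if (is.na(x$rate_kbp_per_discrepancy)) "no discrepancies" else
    sprintf("one differently called base per %.0f Kbp",
            x$rate_kbp_per_discrepancy)
  cat(sprintf("control vs reference: %d base discrepancies (%s); %d missing regions (%s bp), %d extra regions (%s bp)\n",
              x$n_base_discrepancies, rate,
              x$missing$count, format(x$missing$total_bp, big.mark = ","),
              x$extra$count, format(x$extra$total_bp, big.mark = ",")))
  invisible(x)
}

#' Published genome characteristics of the two-genus haloarchaeal study set
#'
#' The deposited genome characteristics of the sequenced Haloferax and
#' Haloarcula assemblies: the seven newly sequenced genomes, the resequenced
#' Haloferax volcanii control, and the two previously published reference
#' genomes (Haloferax volcanii, Haloarcula marismortui). `contigs_fragment`
#' is the shotgun fragment assembly's contig count (> 200 bp);
#' `contigs_final` is the final deposited assembly (after paired-end
#' scaffolding where performed). `status` distinguishes newly sequenced
#' genomes (`"new"`), the resequencing control (`"control"`) and published
#' references (`"reference"`).
#'
#' @return `data.frame` with columns `organism`, `genus`, `status`,
#'   `contigs_fragment`, `contigs_final`, `assembled_bp`, `coverage`,
#'   `cds_count`, `pct_w_function`, `rna_count`, `pct_coding`, `pct_gc`.
#' @export
haloarchaea_genome_table <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
organism genus status contigs_fragment contigs_final assembled_bp coverage cds_count pct_w_function rna_count pct_coding pct_gc
Har._californiae Haloarcula new 168 168 4420514 21 4627 62.5 69 87.00 60.82
Har._sinaiiensis Haloarcula new 140 10 4524388 19 4538 63.1 55 84.62 60.77
Har._vallismortis Haloarcula new 88 88 3930055 24 4084 65.2 84 88.22 61.79
Har._marismortui Haloarcula reference 9 9 4274642 NA 4325 51.8 62 85.83 61.12
Hfx._denitrificans Haloferax new 21 21 3848468 25 3809 70.5 58 85.80 66.27
Hfx._mediterranei Haloferax new 141 5 3905749 26 3942 65.7 62 85.83 60.27
Hfx._mucosum Haloferax new 26 26 3371699 29 3455 66.0 61 86.38 61.84
Hfx._sulfurifontis Haloferax new 29 29 3816558 27 3856 67.6 59 86.56 66.30
Hfx._volcanii_resequenced Haloferax control 145 145 3920004 25 NA NA NA NA NA
Hfx._volcanii Haloferax reference 5 5 4012900 NA 4015 63.3 49 85.56 65.48
")
  df$organism <- gsub("_", " ", df$organism, fixed = TRUE)
  df
}

#' Headline comparison numbers for the published two-genus study set
#'
#' Recomputes, from [haloarchaea_genome_table()], the comparison figures that
#' summarise the two genera: the mean final assembly contig count of the
#' seven newly sequenced genomes; the mean genome size and protein-coding
#' gene (CDS) differences between the Haloferax and Haloarcula groups (each
#' genus's new genomes plus its published reference); the fragment-assembly
#' contig-count ratio between the genera (the three Haloarcula fragment
#' assemblies against the five Haloferax fragment assemblies, resequencing
#' control included — the grouping under which raw shotgun assembly quality
#' is comparable); and the resequencing-control discrepancy rate (13 single
#' base discrepancies over the mean of the control and reference assembly
#' lengths).
#'
#' @return list: `mean_new_contigs`, `pct_size_smaller`, `cds_fewer`,
#'   `pct_cds_fewer`, `contig_ratio`, `discrepancy_rate_kbp`.
#' @export
haloarchaea_comparisons <- function() {
  tbl <- haloarchaea_genome_table()
  stats <- data.frame(genome_id = tbl$organism,
                      assembled_bp = tbl$assembled_bp,
                      cds_count = tbl$cds_count,
                      n_contigs = tbl$contigs_fragment,
                      stringsAsFactors = FALSE)
  hfx <- tbl$organism[tbl$genus == "Haloferax" & tbl$status != "control"]
  har <- tbl$organism[tbl$genus == "Haloarcula"]
  size_cds <- genus_comparison(stats, hfx, har)
  hfx_frag <- tbl$organism[tbl$genus == "Haloferax" & tbl$status != "reference"]
  har_frag <- tbl$organism[tbl$genus == "Haloarcula" & tbl$status == "new"]
  frag <- genus_comparison(stats, hfx_frag, har_frag)
  ctl <- control_discrepancy_summary(
    13,
    tbl$assembled_bp[tbl$organism %in%
                       c("Hfx. volcanii resequenced", "Hfx. volcanii")])
  list(mean_new_contigs = mean(tbl$contigs_final[tbl$status == "new"]),
       pct_size_smaller = size_cds$pct_size_smaller,
       cds_fewer = size_cds$cds_fewer,
       pct_cds_fewer = size_cds$pct_cds_fewer,
       contig_ratio = frag$contig_ratio,
       discrepancy_rate_kbp = ctl$rate_kbp_per_discrepancy)
}
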