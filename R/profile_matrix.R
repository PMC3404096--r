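# Profile-hit filtering, best-profile assignment, presence/absence matrix
# assembly and Manhattan / complete-linkage clustering.
#
# Filter boundaries are strict, taken literally from the screening rule the
# pipeline reproduces: a hit counts only with E-value BELOW the cutoff and
# coverage GREATER THAN the minimum on both the gene and the profile;
# equality fails. The agglomeration is implemented here (rather than through
# stats::hclust) because reproducible CDT export requires a fixed tie-break:
# equal-distance merges are resolved by the smallest pair of cluster creation
# indices, and the smaller-index child is placed on the left.

#' Filter profile hits on E-value and coverage
#'
#' Retains hits with `evalue < e_max` and both coverage fractions strictly
#' greater than `cov_min`. Filtering is monotone: relaxing either threshold
#' never removes a previously kept row.
#'
#' @param hits profile hit table (see [read_profile_hits()]).
#' @param e_max strict E-value upper bound (default 1e-4).
#' @param cov_min strict lower bound on `cov_gene` and `cov_profile`
#'   (default 0.80).
#' @return the retained rows (possibly none).
#' @export
filter_profile_hits <- function(hits, e_max = 1e-4, cov_min = 0.80) {
  keep <- hits$evalue < e_max & hits$cov_gene > cov_min &
    hits$cov_profile > cov_min
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign each gene to its single best profile
#'
#' Among a gene's surviving hits the profile with the minimal E-value wins;
#' ties are broken by higher profile coverage, then higher gene coverage,
#' then lexicographic profile id, so the result is independent of input row
#' order.
#'
#' @param filtered a filtered profile hit table
#'   (see [filter_profile_hits()]).
#' @return `data.frame` with one row per gene: `gene_id`, `profile_id`.
#' @export
assign_best_profile <- function(filtered) {
  if (nrow(filtered) == 0)
    return(data.frame(gene_id = character(), profile_id = character(),
                      stringsAsFactors = FALSE))
  ord <- order(filtered$gene_id, filtered$evalue, -filtered$cov_profile,
               -filtered$cov_gene, filtered$profile_id)
  h <- filtered[ord, , drop = FALSE]
  best <- h[!duplicated(h$gene_id), c("gene_id", "profile_id"), drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Build the binary tribe-by-genome presence/absence matrix
#'
#' Entry (tribe, genome) is 1 iff at least one gene of that genome is
#' assigned to the tribe's profile — binary, not a count. Tribes or genomes
#' with no assignment keep their all-zero row/column so matrix dimensions are
#' reproducible.
#'
#' @param assignments gene-to-profile map from [assign_best_profile()]
#'   (profile ids are tribe ids).
#' @param tribe_ids,genome_ids ordered id vectors fixing the matrix shape.
#' @param gene_genomes named character vector mapping gene id to genome id
#'   (or an annotation table, from which the mapping is taken).
#' @return integer 0/1 matrix with `tribe_ids` rows and `genome_ids` columns.
#' @export
build_presence_matrix <- function(assignments, tribe_ids, genome_ids,
                                  gene_genomes) {
  if (is.data.frame(gene_genomes))
    gene_genomes <- setNames(gene_genomes$genome_id, gene_genomes$gene_id)
  if (anyDuplicated(tribe_ids) || anyDuplicated(genome_ids))
    stop("tribe and genome ids must be unique", call. = FALSE)
  m <- matrix(0L, nrow = length(tribe_ids), ncol = length(genome_ids),
              dimnames = list(tribe_ids, genome_ids))
  if (nrow(assignments) > 0) {
    bad <- setdiff(assignments$profile_id, tribe_ids)
    if (length(bad) > 0)
      stop("assignment to unknown tribe id: ", bad[1], call. = FALSE)
    gn <- unname(gene_genomes[assignments$gene_id])
    if (anyNA(gn))
      stop("assigned gene with unknown genome: ",
           assignments$gene_id[which(is.na(gn))[1]], call. = FALSE)
    bad_gn <- setdiff(gn, genome_ids)
    if (length(bad_gn) > 0)
      stop("assigned gene from genome outside the matrix: ", bad_gn[1],
           call. = FALSE)
    m[cbind(match(assignments$profile_id, tribe_ids),
            match(gn, genome_ids))] <- 1L
  }
  m
}

#' Cluster matrix rows or columns (Manhattan distance, complete linkage)
#'
#' Agglomerative clustering with pairwise item distance equal to the
#' Manhattan (L1) distance between matrix rows (or columns) and cluster
#' distance equal to the maximum pairwise item distance (complete linkage,
#' which is monotone: merge heights never decrease — asserted on every run).
#'
#' Determinism: every cluster carries a creation index (leaves `1..n` in
#' input order, the k-th merged cluster `n + k`); among equally distant pairs
#' the lexicographically smallest index pair merges first, and the
#' smaller-index child is the left child, so leaf order and CDT export are
#' bit-reproducible.
#'
#' @param mat numeric matrix with dimnames.
#' @param axis `"rows"` or `"columns"`.
#' @return object of class `halo_dendrogram`: list with `merge` (m x 2,
#'   hclust sign convention: negative = leaf index, positive = merge step),
#'   `height` (Manhattan units), `order` (leaf indices in display order),
#'   `labels` and `axis`. Convert with [as.hclust.halo_dendrogram()].
#' @export
cluster_matrix <- function(mat, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  x <- if (axis == "rows") mat else t(mat)
  n <- nrow(x)
  if (n < 2) stop("cannot cluster a single-item axis", call. = FALSE)
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- as.matrix(stats::dist(x, method = "manhattan"))
  diag(D) <- Inf
  active <- rep(TRUE, n)     # slot i holds a live cluster
  cl_index <- seq_len(n)     # creation index of the cluster in slot i
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  # signed hclust-style reference for the cluster currently in a slot
  slot_ref <- -seq_len(n)
  # cached per-slot row minimum and its column; complete-linkage distances
  # only ever grow, so a cached minimum stays valid until its column slot is
  # touched by a merge
  rmin <- apply(D, 1, min)
  rarg <- apply(D, 1, which.min)
  for (step in seq_len(n - 1L)) {
    live <- which(active)
    dmin <- min(rmin[live])  # retired slots hold Inf, so they never win
    # tie-break: the pair with the lexicographically smallest creation-index
    # pair = the smallest-index cluster with a dmin partner, joined to its
    # smallest-index dmin partner
    us <- live[rmin[live] == dmin]
    i <- us[which.min(cl_index[us])]
    vs <- which(D[i, ] == dmin)
    j <- vs[which.min(cl_index[vs])]
    # left child = smaller creation index
    if (cl_index[i] > cl_index[j]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(slot_ref[i], slot_ref[j])
    height[step] <- dmin
    # complete linkage: new cluster distance = max of the two children's
    newd <- pmax(D[i, ], D[j, ])
    D[i, ] <- newd; D[, i] <- newd
    D[i, i] <- Inf
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    cl_index[i] <- n + step
    slot_ref[i] <- step
    # refresh caches for slots whose minimum referenced a touched slot
    stale <- which(active & (rarg == i | rarg == j))
    for (k in c(i, stale)) {
      rmin[k] <- min(D[k, ])
      rarg[k] <- which.min(D[k, ])
    }
    rmin[j] <- Inf
  }
  stopifnot(!is.unsorted(height))  # complete linkage is monotone
  dend <- list(merge = merge, height = height,
               order = dendro_leaf_order(merge), labels = labels,
               axis = axis)
  class(dend) <- "halo_dendrogram"
  dend
}

# Leaf order by iterative left-first traversal of the merge tree.
dendro_leaf_order <- function(merge) {
  stack <- nrow(merge)          # root is the last merge
  out <- integer(0)
  while (length(stack) > 0) {
    node <- stack[[1]]; stack <- stack[-1]
    if (node < 0) {
      out <- c(out, -node)
    } else {
      stack <- c(merge[node, 1], merge[node, 2], stack)
    }
  }
  out
}

#' @export
print.halo_dendrogram <- function(x, ...) {
  cat(sprintf("halo_dendrogram (%s): %d leaves, heights %s .. %s (Manhattan, complete linkage)\n",
              x$axis, length(x$labels), format(min(x$height)),
              format(max(x$height))))
  invisible(x)
}

#' Convert a halo_dendrogram to a stats::hclust object
#'
#' @param x a `halo_dendrogram`.
#' @param ... unused.
#' @return an object of class `hclust` (for plotting or cutree).
#' @export
as.hclust.halo_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "complete",
                 dist.method = "manhattan",
                 call = match.call()),
            class = "hclust")
}

#' Run the whole tribe/matrix pipeline on in-memory tables
#'
#' Convenience driver tying the stages together: within-genus tribe
#' construction for both genera, cross-genus joining, consensus function
#' labels, profile-hit filtering, best-profile assignment, and
#' presence/absence matrix assembly over the given tribe id universe.
#'
#' @param genes annotation table.
#' @param sim_hits similarity hit table (within-genus and cross-genus hits
#'   together; they are split by the genus of their endpoint genes).
#' @param profile_hits profile hit table.
#' @param tribe_ids ordered tribe/profile id universe for the matrix rows
#'   (default: the profile ids seen in `profile_hits`, sorted).
#' @param e_max,cov_min filter thresholds, see [filter_profile_hits()].
#' @return list with `tribes_a`, `tribes_b`, `joined` (tribes + joins),
#'   `filtered`, `assignments`, `matrix`.
#' @export
run_tribe_pipeline <- function(genes, sim_hits, profile_hits,
                               tribe_ids = NULL, e_max = 1e-4,
                               cov_min = 0.80) {
  genera <- sort(unique(genes$genus_id))
  if (length(genera) != 2)
    stop("pipeline expects exactly two genera, found: ",
         paste(genera, collapse = ", "), call. = FALSE)
  genus_of <- setNames(genes$genus_id, genes$gene_id)
  gq <- unname(genus_of[sim_hits$query_id])
  gs <- unname(genus_of[sim_hits$subject_id])
  if (anyNA(gq) || anyNA(gs))
    stop("similarity hit references unannotated gene", call. = FALSE)
  within_a <- sim_hits[gq == genera[1] & gs == genera[1], , drop = FALSE]
  within_b <- sim_hits[gq == genera[2] & gs == genera[2], , drop = FALSE]
  cross <- sim_hits[gq != gs, , drop = FALSE]
  tribes_a <- build_within_genus_tribes(within_a, genes, genera[1])
  tribes_b <- build_within_genus_tribes(within_b, genes, genera[2])
  joined <- join_tribes(tribes_a, tribes_b, cross)
  joined$tribes <- tribe_functions(joined$tribes, genes)
  filtered <- filter_profile_hits(profile_hits, e_max = e_max,
                                  cov_min = cov_min)
  assignments <- assign_best_profile(filtered)
  if (is.null(tribe_ids)) tribe_ids <- sort(unique(profile_hits$profile_id))
  genome_ids <- unique(genes$genome_id)
  mat <- build_presence_matrix(assignments, tribe_ids, genome_ids, genes)
  list(tribes_a = tribes_a, tribes_b = tribes_b, joined = joined,
       filtered = filtered, assignments = assignments, matrix = mat)
}
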