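# Ortholog tribe construction and cross-genus joining.
#
# Within a genus, tribes are the connected components of the per-genome-pair
# reciprocal-best-hit (RBH) graph over the similarity hits; genes with no RBH
# edge become singleton tribes, so tribe sets always partition the genus's
# genes. Across genera, a bit score is computed for each pair of tribes by
# averaging the bit scores of all cross hits between their members (both
# search directions pooled) and tribes are joined one-to-one by RBH on those
# averaged scores. Self-hits (query == subject) are dropped before every
# computation since they would inflate averaged scores.

#' Build within-genus ortholog tribes from similarity hits
#'
#' For every ordered (query gene, subject genome) combination the best hit is
#' the one with the highest bit score (ties: lower E-value, then lexicographic
#' subject id). An RBH edge links genes `a`, `b` of different genomes when
#' each is the other's best hit in the partner genome. Tribes are the
#' connected components of the RBH graph; genes without any edge become
#' singleton tribes. The result partitions all genes of the genus.
#'
#' @param hits similarity hit table (see [read_similarity_hits()]) restricted
#'   to genes of the given genus; self-hits and within-genome hits are
#'   ignored.
#' @param genes annotation table covering all hit gene ids.
#' @param genus genus id whose genes are to be partitioned.
#' @return `data.frame` with columns `tribe_id`, `gene_id`, `scope` (the
#'   genus id); one row per gene.
#' @seealso [join_tribes()], [assign_tribe_function()]
#' @export
build_within_genus_tribes <- function(hits, genes, genus) {
  gsel <- genes[genes$genus_id == genus, , drop = FALSE]
  if (nrow(gsel) == 0) stop("no genes annotated for genus: ", genus,
                            call. = FALSE)
  genome_of <- setNames(genes$genome_id, genes$gene_id)
  genus_of <- setNames(genes$genus_id, genes$gene_id)
  ids <- sort(gsel$gene_id)

  if (nrow(hits) > 0) {
    unknown <- setdiff(c(hits$query_id, hits$subject_id), genes$gene_id)
    if (length(unknown) > 0)
      stop("hit references gene of unknown genome: ", unknown[1],
           call. = FALSE)
    wrong <- genus_of[c(hits$query_id, hits$subject_id)] != genus
    if (any(wrong))
      stop("hit references genome outside genus '", genus, "'",
           call. = FALSE)
    hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
    hits <- hits[genome_of[hits$query_id] != genome_of[hits$subject_id], ,
                 drop = FALSE]
  }

  edges <- NULL
  if (nrow(hits) > 0) {
    sgenome <- unname(genome_of[hits$subject_id])
    ord <- order(hits$query_id, sgenome, -hits$bitscore, hits$evalue,
                 hits$subject_id)
    h <- hits[ord, , drop = FALSE]
    best <- h[!duplicated(data.frame(h$query_id, sgenome[ord])), ,
              drop = FALSE]
    # reciprocal: (a -> b) accepted iff (b -> a) is also a best hit
    fwd <- paste(best$query_id, best$subject_id, sep = "\r")
    rev <- paste(best$subject_id, best$query_id, sep = "\r")
    mutual <- best[fwd %in% rev, , drop = FALSE]
    a <- pmin(mutual$query_id, mutual$subject_id)
    b <- pmax(mutual$query_id, mutual$subject_id)
    edges <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  }

  # union-find with path halving over the sorted gene ids
  parent <- seq_along(ids)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(edges) && nrow(edges) > 0) {
    ia <- match(edges$a, ids); ib <- match(edges$b, ids)
    for (k in seq_along(ia)) {
      ra <- uf_find(ia[k]); rb <- uf_find(ib[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_along(ids), uf_find, integer(1))
  # deterministic ids: components ordered by their lexicographically
  # smallest member (== the root, since ids are sorted)
  comp <- match(root, sort(unique(root)))
  out <- data.frame(
    tribe_id = sprintf("%s_SHT%05d", genus, comp),
    gene_id = ids,
    scope = genus,
    stringsAsFactors = FALSE)
  out[order(out$tribe_id, out$gene_id), , drop = FALSE]
}

#' Join tribes across two genera by averaged-bit-score reciprocal best hit
#'
#' The pair score of tribes A (genus a) and B (genus b) is the arithmetic mean
#' of the bit scores of all cross hits between members of A and members of B,
#' pooling both search directions. A join is accepted iff B is A's
#' highest-scoring partner and A is B's (ties broken by higher mean hit
#' coverage, then lexicographic partner tribe id); accepted joins are
#' one-to-one. Tribe pairs with no cross hits have undefined pair score and
#' are never candidates. Joined tribes merge into a single tribe of scope
#' `"joined"`; unjoined tribes pass through unchanged, so the output tribe
#' count is `|A| + |B| - (accepted joins)` and no gene is lost.
#'
#' @param tribes_a,tribes_b within-genus tribe tables from
#'   [build_within_genus_tribes()] for the two genera.
#' @param cross_hits similarity hits connecting genes of the two genera (both
#'   directions allowed); a hit internal to one genus is an error.
#' @return list with `tribes` (membership `data.frame`: `tribe_id`,
#'   `gene_id`, `scope`) and `joins` (`data.frame`: `tribe_a`, `tribe_b`,
#'   `pair_score`).
#' @export
join_tribes <- function(tribes_a, tribes_b, cross_hits) {
  tribe_of_a <- setNames(tribes_a$tribe_id, tribes_a$gene_id)
  tribe_of_b <- setNames(tribes_b$tribe_id, tribes_b$gene_id)
  joins <- data.frame(tribe_a = character(), tribe_b = character(),
                      pair_score = numeric(), stringsAsFactors = FALSE)
  if (nrow(cross_hits) > 0) {
    cross_hits <- cross_hits[cross_hits$query_id != cross_hits$subject_id, ,
                             drop = FALSE]
  }
  if (nrow(cross_hits) > 0) {
    q_in_a <- cross_hits$query_id %in% names(tribe_of_a)
    q_in_b <- cross_hits$query_id %in% names(tribe_of_b)
    s_in_a <- cross_hits$subject_id %in% names(tribe_of_a)
    s_in_b <- cross_hits$subject_id %in% names(tribe_of_b)
    unknown <- !((q_in_a | q_in_b) & (s_in_a | s_in_b))
    if (any(unknown))
      stop("cross hit references gene in neither tribe set: ",
           cross_hits$query_id[which(unknown)[1]], call. = FALSE)
    internal <- (q_in_a & s_in_a) | (q_in_b & s_in_b)
    if (any(internal))
      stop("cross hit internal to one genus: ",
           cross_hits$query_id[which(internal)[1]], " -> ",
           cross_hits$subject_id[which(internal)[1]], call. = FALSE)
    # orient every hit as (tribe in a, tribe in b); both directions pool
    ta <- ifelse(q_in_a, tribe_of_a[cross_hits$query_id],
                 tribe_of_a[cross_hits$subject_id])
    tb <- ifelse(q_in_b, tribe_of_b[cross_hits$query_id],
                 tribe_of_b[cross_hits$subject_id])
    cov <- rowMeans(cbind(cross_hits$q_cov, cross_hits$s_cov), na.rm = TRUE)
    cov[is.nan(cov)] <- 0
    key <- paste(ta, tb, sep = "\r")
    score <- tapply(cross_hits$bitscore, key, mean)
    mcov <- tapply(cov, key, mean)
    pair_ids <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
    pairs <- data.frame(tribe_a = pair_ids[, 1], tribe_b = pair_ids[, 2],
                        pair_score = as.numeric(score),
                        mean_cov = as.numeric(mcov),
                        stringsAsFactors = FALSE)
    best_partner <- function(df, from, to) {
      ord <- order(df[[from]], -df$pair_score, -df$mean_cov, df[[to]])
      d <- df[ord, , drop = FALSE]
      d[!duplicated(d[[from]]), c(from, to, "pair_score"), drop = FALSE]
    }
    best_a <- best_partner(pairs, "tribe_a", "tribe_b")
    best_b <- best_partner(pairs, "tribe_b", "tribe_a")
    fwd <- paste(best_a$tribe_a, best_a$tribe_b, sep = "\r")
    rev <- paste(best_b$tribe_a, best_b$tribe_b, sep = "\r")
    acc <- best_a[fwd %in% rev, , drop = FALSE]
    joins <- data.frame(tribe_a = acc$tribe_a, tribe_b = acc$tribe_b,
                        pair_score = acc$pair_score,
                        stringsAsFactors = FALSE)
    joins <- joins[order(joins$tribe_a), , drop = FALSE]
    rownames(joins) <- NULL
  }
  joined_id <- sprintf("joint%05d", seq_len(nrow(joins)))
  map_a <- setNames(joined_id, joins$tribe_a)
  map_b <- setNames(joined_id, joins$tribe_b)
  relabel <- function(tr, map) {
    hit <- tr$tribe_id %in% names(map)
    tr$scope[hit] <- "joined"
    tr$tribe_id[hit] <- unname(map[tr$tribe_id[hit]])
    tr
  }
  out <- rbind(relabel(tribes_a, map_a), relabel(tribes_b, map_b))
  out <- out[order(out$tribe_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  list(tribes = out, joins = joins)
}

#' Consensus function label of a tribe
#'
#' The most commonly occurring product annotation among the tribe's member
#' genes; ties are broken by the lexicographically smallest label.
#'
#' @param members character vector of member gene ids.
#' @param genes annotation table containing every member.
#' @return the modal product string.
#' @export
assign_tribe_function <- function(members, genes) {
  if (length(members) == 0) stop("tribe has no members", call. = FALSE)
  prod <- setNames(genes$product, genes$gene_id)
  missing <- setdiff(members, names(prod))
  if (length(missing) > 0)
    stop("tribe member missing from annotation table: ", missing[1],
         call. = FALSE)
  labels <- unname(prod[members])
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  sort(top)[1]
}

#' Consensus function labels for a whole tribe table
#'
#' @param tribes membership `data.frame` (`tribe_id`, `gene_id`, ...).
#' @param genes annotation table.
#' @return the tribe table with a `function_label` column added.
#' @export
tribe_functions <- function(tribes, genes) {
  labs <- vapply(split(tribes$gene_id, tribes$tribe_id),
                 assign_tribe_function, character(1), genes = genes)
  tribes$function_label <- unname(labs[tribes$tribe_id])
  tribes
}

#' Read or write a tribe membership table
#'
#' Tab-separated with header: `tribe_id`, `gene_id`, `scope` and optionally
#' `function_label`.
#'
#' @param path file path.
#' @export
read_tribes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tribe_id", "gene_id", "scope")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("tribe table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_tribes
#' @param tribes tribe membership `data.frame` to write.
#' @export
write_tribes <- function(tribes, path) {
  write.table(tribes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
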