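# Seed-reproducible synthetic two-genus pangenome generator with known tribe
# truth. The generator stands in for deposited genome assemblies: it produces
# the per-genome gene annotation tables, all-vs-all similarity hit tables,
# profile-vs-proteome hit tables and species tree that the downstream tribe /
# matrix / enrichment / screen stages consume, together with the ground truth
# (tribe membership, per-branch gain/loss event log, presence matrix) those
# stages are validated against.

# Controlled vocabulary of product strings so annotation screens have known
# truth counts. "hypothetical protein" is deliberately over-represented.
PRODUCT_VOCABULARY <- c(
  "hypothetical protein",
  "TATA-binding protein transcription initiation factor",
  "transcription factor B",
  "cellulase family protein",
  "bacteriorhodopsin",
  "halorhodopsin",
  "sensory rhodopsin",
  "DNA sliding clamp (PCNA)",
  "CRISPR-associated protein Cas1",
  "CRISPR-associated protein Cas3",
  "signal transduction histidine kinase",
  "CheY-like response regulator receiver protein",
  "ABC transporter permease",
  "heavy metal translocating P-type ATPase",
  "gluconolactonase",
  "6-phosphogluconate dehydratase",
  "methylaspartate mutase subunit E",
  "methylaspartate ammonia-lyase",
  "polyhydroxyalkanoate synthase",
  "isocitrate lyase",
  "malate synthase",
  "universal stress protein UspA",
  "DNA-directed RNA polymerase subunit B''",
  "30S ribosomal protein S4",
  "transcriptional regulator, TrmB family",
  "sodium/proton antiporter",
  "potassium uptake protein TrkA",
  "phosphate ABC transporter substrate-binding protein",
  "thermosome subunit",
  "DNA repair and recombination protein RadA"
)

#' Simulation parameters for the synthetic two-genus pangenome
#'
#' Bundles and validates every knob of the generator. Identical parameter sets
#' (including `seed`) produce byte-identical outputs.
#'
#' The defaults emulate the structure of a sequenced two-genus haloarchaeal
#' data set: five genomes in one genus and four in the other; enough shared
#' core tribes and genus-specific tribes that each genome carries roughly
#' 3,400 genes; a ladderized species tree in which one three-genome clade of
#' genus A suffers a boosted gene-loss rate; and COG signal-transduction (T)
#' fractions of 3.0% in genus A versus 4.2% in genus B.
#'
#' @param n_genomes_per_genus named integer vector (length 2): genomes per
#'   genus; names are the genus ids.
#' @param n_core_tribes number of tribes present at the root of the whole
#'   tree (shared ancestry across both genera).
#' @param n_genus_tribes named integer vector: tribes originating at each
#'   genus ancestor (genus-specific).
#' @param loss_rate per-tribe per-branch probability that a present tribe is
#'   lost.
#' @param gain_rate per-tribe per-branch probability that an absent tribe is
#'   (re)gained.
#' @param clade_loss_boost multiplier (>= 1) applied to `loss_rate` on every
#'   branch inside the designated clade (including its stem).
#' @param clade_genomes genome ids forming the designated elevated-loss clade;
#'   default: the last three genomes of the first genus (a proper clade of the
#'   default ladder tree).
#' @param cog_effect named list mapping COG category letters to a named
#'   numeric vector of per-genus mean fractions of genes in that category.
#' @param baseline_cog_fraction total fraction of genes carrying any COG
#'   letter (the remainder after the `cog_effect` categories is spread evenly
#'   over the other letters).
#' @param score_noise_sd standard deviation (bits) of the Gaussian noise added
#'   to within-tribe bit scores; 0 gives perfectly separated score
#'   distributions.
#' @param noise_hit_rate expected number of spurious cross-tribe similarity
#'   hits emitted per gene (0 for a noiseless run).
#' @param decoy_rate expected number of spurious profile hits per gene,
#'   spanning the filter thresholds on both sides.
#' @param mean_gene_length,sd_gene_length mean / sd of per-tribe protein
#'   length (aa), truncated below at 60.
#' @param tree optional user Newick string overriding the default ladderized
#'   topology (leaf labels must be the genome ids `<genus>_<i>`).
#' @param seed integer random seed (< 2^31 - 10; derived sub-seeds are used by
#'   the emitters).
#' @return an object of class `halo_sim_params` (a validated list).
#' @seealso [generate_pangenome()]
#' @export
sim_params <- function(n_genomes_per_genus = c(genusA = 5L, genusB = 4L),
                       n_core_tribes = 2400L,
                       n_genus_tribes = c(genusA = 1000L, genusB = 1000L),
                       loss_rate = 0.02,
                       gain_rate = 0.01,
                       clade_loss_boost = 10,
                       clade_genomes = NULL,
                       cog_effect = list(T = c(genusA = 0.030, genusB = 0.042)),
                       baseline_cog_fraction = 0.67,
                       score_noise_sd = 5,
                       noise_hit_rate = 0.2,
                       decoy_rate = 0.1,
                       mean_gene_length = 300,
                       sd_gene_length = 80,
                       tree = NULL,
                       seed = 1L) {
  n_genomes_per_genus <- check_count(n_genomes_per_genus,
                                     "n_genomes_per_genus", min = 1L)
  if (length(n_genomes_per_genus) != 2 || is.null(names(n_genomes_per_genus)))
    stop_field("n_genomes_per_genus", "must be a named vector of length 2")
  genera <- names(n_genomes_per_genus)
  n_core_tribes <- check_count(n_core_tribes, "n_core_tribes")
  n_genus_tribes <- check_count(n_genus_tribes, "n_genus_tribes")
  if (!setequal(names(n_genus_tribes), genera))
    stop_field("n_genus_tribes", "names must match the genera")
  n_genus_tribes <- n_genus_tribes[genera]
  check_prob(loss_rate, "loss_rate")
  check_prob(gain_rate, "gain_rate")
  if (!is.numeric(clade_loss_boost) || clade_loss_boost < 1)
    stop_field("clade_loss_boost", "must be a multiplier >= 1")
  check_prob(min(1, loss_rate * clade_loss_boost), "loss_rate")
  if (loss_rate * clade_loss_boost > 1)
    stop_field("clade_loss_boost", "loss_rate * clade_loss_boost exceeds 1")
  if (!is.list(cog_effect) ||
      (length(cog_effect) > 0 && is.null(names(cog_effect))))
    stop_field("cog_effect", "must be a named list of per-genus fractions")
  bad <- setdiff(names(cog_effect), COG_ALPHABET)
  if (length(bad) > 0)
    stop_field("cog_effect", paste("unknown COG letter(s):",
                                   paste(bad, collapse = ", ")))
  for (letter in names(cog_effect)) {
    v <- cog_effect[[letter]]
    if (!setequal(names(v), genera))
      stop_field("cog_effect", sprintf("entry '%s' must name both genera", letter))
    for (g in genera) check_prob(v[[g]], sprintf("cog_effect$%s[%s]", letter, g))
  }
  check_prob(baseline_cog_fraction, "baseline_cog_fraction")
  for (g in genera) {
    tot <- sum(vapply(cog_effect, function(v) v[[g]], numeric(1)))
    if (tot > baseline_cog_fraction)
      stop_field("cog_effect",
                 sprintf("fractions for genus '%s' exceed baseline_cog_fraction", g))
  }
  if (!is.numeric(score_noise_sd) || score_noise_sd < 0)
    stop_field("score_noise_sd", "must be a non-negative real")
  if (!is.numeric(noise_hit_rate) || noise_hit_rate < 0)
    stop_field("noise_hit_rate", "must be a non-negative real")
  if (!is.numeric(decoy_rate) || decoy_rate < 0)
    stop_field("decoy_rate", "must be a non-negative real")
  if (!is.numeric(mean_gene_length) || mean_gene_length < 60)
    stop_field("mean_gene_length", "must be >= 60 aa")
  if (!is.numeric(sd_gene_length) || sd_gene_length < 0)
    stop_field("sd_gene_length", "must be non-negative")
  seed <- check_count(seed, "seed")
  if (seed > .Machine$integer.max - 10L)
    stop_field("seed", "must be below 2^31 - 10")
  genome_ids <- unlist(lapply(genera, function(g)
    sprintf("%s_%02d", g, seq_len(n_genomes_per_genus[[g]]))), use.names = FALSE)
  if (is.null(clade_genomes)) {
    gA <- sprintf("%s_%02d", genera[1], seq_len(n_genomes_per_genus[[1]]))
    clade_genomes <- if (length(gA) >= 3) tail(gA, 3) else gA
  }
  if (!all(clade_genomes %in% genome_ids))
    stop_field("clade_genomes", "must be a subset of the genome ids")
  p <- list(n_genomes_per_genus = n_genomes_per_genus,
            genera = genera, genome_ids = genome_ids,
            n_core_tribes = n_core_tribes, n_genus_tribes = n_genus_tribes,
            loss_rate = loss_rate, gain_rate = gain_rate,
            clade_loss_boost = clade_loss_boost,
            clade_genomes = clade_genomes,
            cog_effect = cog_effect,
            baseline_cog_fraction = baseline_cog_fraction,
            score_noise_sd = score_noise_sd,
            noise_hit_rate = noise_hit_rate, decoy_rate = decoy_rate,
            mean_gene_length = mean_gene_length,
            sd_gene_length = sd_gene_length,
            tree = tree, seed = seed)
  class(p) <- "halo_sim_params"
  p
}

# Ladderized Newick for one genus: first genome is the outermost tip, the last
# tips form the deepest nested clades. All branch lengths 1.
ladder_newick <- function(tips) {
  if (length(tips) == 1) return(tips)
  sprintf("(%s:1,%s:1)", ladder_newick(tips[-1]), tips[1])
}

#' Default species tree for a parameter set
#'
#' Two ladderized genus subtrees joined at the root, mirroring a five-plus-four
#' genome two-genus study design; all branch lengths 1. A user-supplied Newick
#' string in `params$tree` overrides it.
#'
#' @param params a [sim_params()] object.
#' @return an [ape::phylo] tree whose tips are the genome ids.
#' @export
default_species_tree <- function(params) {
  nwk <- params$tree
  if (is.null(nwk)) {
    sub <- vapply(params$genera, function(g) {
      tips <- sprintf("%s_%02d", g, seq_len(params$n_genomes_per_genus[[g]]))
      if (length(tips) == 1) paste0(tips, ":1") else
        paste0(ladder_newick(tips), ":1")
    }, character(1))
    nwk <- sprintf("(%s,%s);", sub[1], sub[2])
  }
  tr <- ape::read.tree(text = nwk)
  if (is.null(tr) || !setequal(tr$tip.label, params$genome_ids))
    stop_field("tree", "Newick must contain exactly the genome ids as tips")
  tr
}

# Edge indices (rows of tree$edge) lying inside the clade subtree spanned by
# `clade_genomes`, including the stem edge leading to its MRCA.
clade_edge_set <- function(tree, clade_genomes) {
  tips <- match(clade_genomes, tree$tip.label)
  if (length(tips) == 1) {
    return(which(tree$edge[, 2] == tips))
  }
  mrca <- ape::getMRCA(tree, tips)
  nodes <- mrca
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% nodes, 2]
    grown <- union(nodes, kids)
    if (length(grown) == length(nodes)) break
    nodes <- grown
  }
  which(tree$edge[, 2] %in% nodes)
}

# Simulate presence along the tree for one block of tribes sharing an origin
# node. Returns presence at the leaves plus the per-branch toggle events.
simulate_block <- function(tree, origin, tribe_ids, loss_rate, gain_rate,
                           boost_edges, clade_loss_boost) {
  n_tribes <- length(tribe_ids)
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  edge <- tree$edge  # tree is in cladewise order: parents precede children
  preorder <- seq_len(nrow(edge))
  presence <- matrix(FALSE, nrow = n_tribes, ncol = n_nodes)
  presence[, origin] <- TRUE
  # restrict to edges inside the origin's subtree
  in_subtree <- rep(FALSE, n_nodes)
  in_subtree[origin] <- TRUE
  events <- vector("list", nrow(edge))
  node_name <- c(tree$tip.label,
                 sprintf("node%d", ape::Ntip(tree) + seq_len(tree$Nnode)))
  for (e in preorder) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    if (!in_subtree[parent]) next
    in_subtree[child] <- TRUE
    p <- presence[, parent]
    rate_loss <- if (e %in% boost_edges) loss_rate * clade_loss_boost else loss_rate
    u <- runif(n_tribes)
    toggled <- (p & u < rate_loss) | (!p & u < gain_rate)
    presence[, child] <- xor(p, toggled)
    if (any(toggled)) {
      events[[e]] <- data.frame(tribe_id = tribe_ids[toggled],
                                branch = node_name[child],
                                event = ifelse(p[toggled], "loss", "gain"),
                                stringsAsFactors = FALSE)
    }
  }
  ntip <- ape::Ntip(tree)
  leaf_presence <- presence[, seq_len(ntip), drop = FALSE]
  colnames(leaf_presence) <- tree$tip.label
  rownames(leaf_presence) <- tribe_ids
  list(presence = leaf_presence,
       events = do.call(rbind, events[!vapply(events, is.null, logical(1))]))
}

#' Generate a synthetic two-genus pangenome with known truth
#'
#' Simulates tribe gain and loss as independent per-branch Bernoulli toggles
#' over the species tree: core tribes originate at the root, genus-specific
#' tribes at their genus ancestor, and branches inside the designated clade
#' (stem included) lose tribes at `clade_loss_boost` times the background
#' rate. Each (genome, tribe) presence yields exactly one gene, so every gene
#' belongs to exactly one true tribe. Tribe function labels and protein
#' lengths are drawn once per tribe from a controlled vocabulary.
#'
#' Deterministic: identical parameters (including seed) give identical truth
#' objects and, through the `emit_*` functions, byte-identical output tables.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `halo_pangenome`: a list with elements
#'   `params`, `tree` (phylo), `genomes` (data.frame genome_id/genus_id),
#'   `tribes` (data.frame tribe_id/origin/function_label/length_aa),
#'   `presence` (logical tribes x genomes matrix), `events` (per-branch
#'   gain/loss log) and `genes` (data.frame gene_id/genome_id/genus_id/
#'   tribe_id).
#' @export
generate_pangenome <- function(params) {
  if (!inherits(params, "halo_sim_params"))
    stop("params must come from sim_params()", call. = FALSE)
  set.seed(params$seed)
  tree <- ape::reorder.phylo(default_species_tree(params), "cladewise")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  genera <- params$genera
  genome_df <- data.frame(
    genome_id = params$genome_ids,
    genus_id = rep(genera, params$n_genomes_per_genus[genera]),
    stringsAsFactors = FALSE)

  boost_edges <- if (params$clade_loss_boost > 1)
    clade_edge_set(tree, params$clade_genomes) else integer(0)

  blocks <- list()
  if (params$n_core_tribes > 0) {
    blocks$core <- list(origin = root,
                        ids = sprintf("core%05d", seq_len(params$n_core_tribes)))
  }
  for (g in genera) {
    n <- params$n_genus_tribes[[g]]
    if (n == 0) next
    tips <- genome_df$genome_id[genome_df$genus_id == g]
    origin <- if (length(tips) == 1) match(tips, tree$tip.label) else
      ape::getMRCA(tree, match(tips, tree$tip.label))
    blocks[[g]] <- list(origin = origin,
                        ids = sprintf("%s_tribe%05d", g, seq_len(n)))
  }

  presence <- matrix(FALSE, nrow = 0, ncol = ntip,
                     dimnames = list(NULL, tree$tip.label))
  events <- list()
  for (b in blocks) {
    sim <- simulate_block(tree, b$origin, b$ids, params$loss_rate,
                          params$gain_rate, boost_edges,
                          params$clade_loss_boost)
    presence <- rbind(presence, sim$presence)
    events[[length(events) + 1L]] <- sim$events
  }
  events <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(tribe_id = character(), branch = character(),
                         event = character(), stringsAsFactors = FALSE)
  presence <- presence[, genome_df$genome_id, drop = FALSE]

  tribe_ids <- rownames(presence)
  origin_lab <- c(rep("core", params$n_core_tribes),
                  rep(genera, params$n_genus_tribes[genera]))
  tribes <- data.frame(
    tribe_id = tribe_ids,
    origin = origin_lab,
    function_label = sample(PRODUCT_VOCABULARY, length(tribe_ids),
                            replace = TRUE,
                            prob = c(0.4, rep(0.6 / (length(PRODUCT_VOCABULARY) - 1),
                                              length(PRODUCT_VOCABULARY) - 1))),
    length_aa = pmax(60L, round(rnorm(length(tribe_ids),
                                      params$mean_gene_length,
                                      params$sd_gene_length))),
    stringsAsFactors = FALSE)

  # one gene per (genome, tribe) presence, numbered within genome
  idx <- which(presence, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  genes <- data.frame(
    genome_id = genome_df$genome_id[idx[, 2]],
    tribe_id = tribe_ids[idx[, 1]],
    stringsAsFactors = FALSE)
  gnum <- sequence(rle(genes$genome_id)$lengths)
  genes$gene_id <- sprintf("%s_g%05d", genes$genome_id, gnum)
  genes$genus_id <- genome_df$genus_id[match(genes$genome_id,
                                             genome_df$genome_id)]
  genes <- genes[c("gene_id", "genome_id", "genus_id", "tribe_id")]
  rownames(genes) <- NULL

  truth <- list(params = params, tree = tree,
                genomes = genome_df, tribes = tribes,
                presence = presence, events = events, genes = genes)
  class(truth) <- "halo_pangenome"
  truth
}

#' @export
print.halo_pangenome <- function(x, ...) {
  cat(sprintf("synthetic pangenome: %d tribes, %d genomes (%s), %d genes, %d gain/loss events\n",
              nrow(x$tribes), nrow(x$genomes),
              paste(sprintf("%s: %d", x$params$genera,
                            x$params$n_genomes_per_genus[x$params$genera]),
                    collapse = ", "),
              nrow(x$genes), nrow(x$events)))
  invisible(x)
}

#' Truth presence/absence matrix of a synthetic pangenome
#'
#' @param truth a `halo_pangenome` object.
#' @return integer 0/1 matrix, tribes x genomes.
#' @export
truth_presence_matrix <- function(truth) {
  m <- truth$presence * 1L
  storage.mode(m) <- "integer"
  m
}

#' Emit an all-vs-all similarity hit table from a synthetic pangenome
#'
#' Every ordered pair of distinct genes in the same tribe (within and across
#' genera) receives a high bit score centred on 1.5 bits per residue of the
#' tribe's protein length, with Gaussian noise of `score_noise_sd`; spurious
#' cross-tribe pairs (expected `noise_hit_rate` per gene) receive low scores
#' in [20, 50] bits. With `score_noise_sd = 0` every within-tribe score
#' strictly exceeds every cross-tribe score. E-values are a deterministic
#' monotone transform of the bit score; only their ordering matters
#' downstream.
#'
#' @param truth a `halo_pangenome` object.
#' @param params the [sim_params()] the truth was generated with.
#' @return similarity hit `data.frame` (`query_id`, `subject_id`, `bitscore`,
#'   `evalue`, `q_cov`, `s_cov`).
#' @export
emit_similarity_hits <- function(truth, params) {
  set.seed(params$seed + 1L)
  genes <- truth$genes
  empty <- data.frame(query_id = character(), subject_id = character(),
                      bitscore = numeric(), evalue = numeric(),
                      q_cov = numeric(), s_cov = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(genes) == 0) return(empty)
  key <- data.frame(gene_id = genes$gene_id, tribe_id = genes$tribe_id,
                    stringsAsFactors = FALSE)
  pairs <- merge(key, key, by = "tribe_id", suffixes = c("_q", "_s"))
  pairs <- pairs[pairs$gene_id_q != pairs$gene_id_s, , drop = FALSE]
  pairs <- pairs[order(pairs$gene_id_q, pairs$gene_id_s), , drop = FALSE]
  tlen <- setNames(truth$tribes$length_aa, truth$tribes$tribe_id)
  n_in <- nrow(pairs)
  within <- if (n_in > 0) data.frame(
    query_id = pairs$gene_id_q, subject_id = pairs$gene_id_s,
    bitscore = pmax(60, 1.5 * unname(tlen[pairs$tribe_id]) +
                      rnorm(n_in, 0, params$score_noise_sd)),
    q_cov = runif(n_in, 0.85, 1.0), s_cov = runif(n_in, 0.85, 1.0),
    stringsAsFactors = FALSE) else NULL

  n_noise <- if (params$noise_hit_rate > 0)
    rpois(1, params$noise_hit_rate * nrow(genes)) else 0L
  noise <- NULL
  if (n_noise > 0 && nrow(genes) > 1) {
    qi <- sample.int(nrow(genes), n_noise, replace = TRUE)
    si <- sample.int(nrow(genes), n_noise, replace = TRUE)
    keep <- genes$tribe_id[qi] != genes$tribe_id[si]
    qi <- qi[keep]; si <- si[keep]
    if (length(qi) > 0) {
      noise <- data.frame(
        query_id = genes$gene_id[qi], subject_id = genes$gene_id[si],
        bitscore = runif(length(qi), 20, 50),
        q_cov = runif(length(qi), 0.2, 0.7),
        s_cov = runif(length(qi), 0.2, 0.7),
        stringsAsFactors = FALSE)
      noise <- noise[!duplicated(noise[c("query_id", "subject_id")]), ,
                     drop = FALSE]
    }
  }
  hits <- rbind(within, noise)
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  # deterministic monotone transform of bit score; capped to sane range
  hits$evalue <- pmin(10, pmax(1e-180, 10^(4 - hits$bitscore / 3)))
  rownames(hits) <- NULL
  hits[c("query_id", "subject_id", "bitscore", "evalue", "q_cov", "s_cov")]
}

#' Emit a profile-vs-proteome hit table from a synthetic pangenome
#'
#' One profile per true tribe (profile id = tribe id), emulating profile HMMs
#' built from tribe alignments. Every gene hits its own tribe's profile with
#' E-value below 1e-8 and coverages above 0.9; decoy hits (expected
#' `decoy_rate` per gene, against other tribes' profiles) have E-values in
#' [1e-7, 1] and coverages in [0.5, 1.0], spanning the downstream filter
#' thresholds on both sides. Because every gene's true hit dominates any
#' decoy, best-E-value assignment is unaffected by decoys.
#'
#' @inheritParams emit_similarity_hits
#' @return profile hit `data.frame` (`gene_id`, `profile_id`, `evalue`,
#'   `cov_gene`, `cov_profile`).
#' @export
emit_profile_hits <- function(truth, params) {
  set.seed(params$seed + 2L)
  genes <- truth$genes
  if (nrow(genes) == 0)
    return(data.frame(gene_id = character(), profile_id = character(),
                      evalue = numeric(), cov_gene = numeric(),
                      cov_profile = numeric(), stringsAsFactors = FALSE))
  n <- nrow(genes)
  true_hits <- data.frame(
    gene_id = genes$gene_id, profile_id = genes$tribe_id,
    evalue = 10^-runif(n, 8, 30),
    cov_gene = runif(n, 0.92, 1.0), cov_profile = runif(n, 0.92, 1.0),
    stringsAsFactors = FALSE)
  decoys <- NULL
  n_decoy <- if (params$decoy_rate > 0) rpois(1, params$decoy_rate * n) else 0L
  if (n_decoy > 0 && nrow(truth$tribes) > 1) {
    gi <- sample.int(n, n_decoy, replace = TRUE)
    pi <- sample(truth$tribes$tribe_id, n_decoy, replace = TRUE)
    keep <- genes$tribe_id[gi] != pi
    gi <- gi[keep]; pi <- pi[keep]
    if (length(gi) > 0) {
      decoys <- data.frame(
        gene_id = genes$gene_id[gi], profile_id = pi,
        evalue = 10^-runif(length(gi), 0, 7),
        cov_gene = runif(length(gi), 0.5, 1.0),
        cov_profile = runif(length(gi), 0.5, 1.0),
        stringsAsFactors = FALSE)
      decoys <- decoys[!duplicated(decoys[c("gene_id", "profile_id")]), ,
                       drop = FALSE]
    }
  }
  out <- rbind(true_hits, decoys)
  rownames(out) <- NULL
  out
}

#' Emit the gene annotation table of a synthetic pangenome
#'
#' Product strings are the tribe function labels (controlled vocabulary, so
#' annotation screens have known truth counts). Each gene draws at most one
#' COG category letter: the letters named in `cog_effect` with their per-genus
#' mean probabilities, the remaining mass up to `baseline_cog_fraction` spread
#' evenly over the other letters, and no letter otherwise. Per-genome category
#' fractions therefore have expectation equal to the genus mean.
#'
#' @inheritParams emit_similarity_hits
#' @return annotation `data.frame` (`gene_id`, `genome_id`, `genus_id`,
#'   `product`, `cog`, `length_aa`).
#' @export
emit_annotations <- function(truth, params) {
  set.seed(params$seed + 3L)
  genes <- truth$genes
  tribes <- truth$tribes
  out <- data.frame(
    gene_id = genes$gene_id, genome_id = genes$genome_id,
    genus_id = genes$genus_id,
    product = tribes$function_label[match(genes$tribe_id, tribes$tribe_id)],
    cog = character(nrow(genes)),
    length_aa = tribes$length_aa[match(genes$tribe_id, tribes$tribe_id)],
    stringsAsFactors = FALSE)
  if (nrow(out) == 0) return(out)
  effect_letters <- names(params$cog_effect)
  other_letters <- setdiff(COG_ALPHABET, effect_letters)
  for (g in params$genera) {
    sel <- out$genus_id == g
    if (!any(sel)) next
    p_eff <- vapply(params$cog_effect, function(v) v[[g]], numeric(1))
    p_other <- rep((params$baseline_cog_fraction - sum(p_eff)) /
                     length(other_letters), length(other_letters))
    probs <- c(p_eff, p_other, 1 - params$baseline_cog_fraction)
    draws <- sample(c(effect_letters, other_letters, ""),
                    sum(sel), replace = TRUE, prob = probs)
    out$cog[sel] <- draws
  }
  out
}

#' Write every external table of a synthetic pangenome to a directory
#'
#' Emits the gene annotation TSV, the 12-column similarity hit table, the
#' profile-hit TSV, the species tree (Newick) and the truth presence/absence
#' matrix (TSV) via the package's format writers.
#'
#' @inheritParams emit_similarity_hits
#' @param outdir output directory (created if absent).
#' @return invisibly, a named list of the paths written.
#' @export
write_pangenome <- function(truth, params, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- emit_annotations(truth, params)
  sim <- emit_similarity_hits(truth, params)
  prof <- emit_profile_hits(truth, params)
  paths <- list(
    annotations = file.path(outdir, "annotations.tsv"),
    similarity_hits = file.path(outdir, "similarity_hits.tsv"),
    profile_hits = file.path(outdir, "profile_hits.tsv"),
    tree = file.path(outdir, "species_tree.nwk"),
    truth_matrix = file.path(outdir, "truth_matrix.tsv"))
  write_annotations(ann, paths$annotations)
  write_similarity_hits(sim, ann, paths$similarity_hits)
  write_profile_hits(prof, paths$profile_hits)
  ape::write.tree(truth$tree, file = paths$tree)
  tm <- truth_presence_matrix(truth)
  write.table(data.frame(tribe_id = rownames(tm), tm, check.names = FALSE),
              paths$truth_matrix, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
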