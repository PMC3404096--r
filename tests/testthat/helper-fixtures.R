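# Shared fixtures and independent oracles. The oracles deliberately use
# different algorithms from the package implementation (brute-force
# enumeration, from-scratch distance recomputation) so the two routes can
# disagree when either is wrong.

small_params <- function(seed = 1L, ...) {
  args <- list(n_genomes_per_genus = c(genusA = 5L, genusB = 4L),
               n_core_tribes = 40L,
               n_genus_tribes = c(genusA = 12L, genusB = 12L),
               seed = seed)
  do.call(sim_params, utils::modifyList(args, list(...)))
}

noiseless_params <- function(seed = 1L, ...) {
  small_params(seed = seed, score_noise_sd = 0, noise_hit_rate = 0,
               decoy_rate = 0, ...)
}

toy_genes <- function(gene_id, genome_id, genus_id = "genusA",
                      product = "hypothetical protein", cog = "",
                      length_aa = 100L) {
  data.frame(gene_id = gene_id, genome_id = genome_id, genus_id = genus_id,
             product = product, cog = cog, length_aa = length_aa,
             stringsAsFactors = FALSE)
}

toy_hits <- function(query_id, subject_id, bitscore, evalue = NULL,
                     q_cov = 0.9, s_cov = 0.9) {
  if (is.null(evalue)) evalue <- 2^-bitscore
  k <- length(query_id)
  data.frame(query_id = query_id, subject_id = subject_id,
             bitscore = rep_len(bitscore, k), evalue = rep_len(evalue, k),
             q_cov = rep_len(q_cov, k), s_cov = rep_len(s_cov, k),
             stringsAsFactors = FALSE)
}

# tribe membership table -> canonical set-of-sets (order-free comparison)
canonical_membership <- function(tribes) {
  sets <- lapply(split(tribes$gene_id, tribes$tribe_id), sort)
  unname(sets[order(vapply(sets, `[`, character(1), 1))])
}

# --- clustering oracle: O(n^3) agglomeration recomputing every cluster
# distance from scratch as the max pairwise Manhattan distance -------------
oracle_complete_linkage <- function(x) {
  n <- nrow(x)
  manh <- function(i, j) sum(abs(x[i, ] - x[j, ]))
  clusters <- lapply(seq_len(n), function(i)
    list(members = i, index = i, ref = -i))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    k <- length(clusters)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- max(vapply(clusters[[i]]$members, function(a)
          max(vapply(clusters[[j]]$members, function(b) manh(a, b),
                     numeric(1))), numeric(1)))
        pair <- sort(c(clusters[[i]]$index, clusters[[j]]$index))
        better <- is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
             (pair[1] < best$pair[1] ||
                (pair[1] == best$pair[1] && pair[2] < best$pair[2])))
        if (better) best <- list(d = d, pair = pair, i = i, j = j)
      }
    }
    ci <- clusters[[best$i]]; cj <- clusters[[best$j]]
    left <- if (ci$index < cj$index) ci else cj
    right <- if (ci$index < cj$index) cj else ci
    merge[step, ] <- c(left$ref, right$ref)
    height[step] <- best$d
    clusters[[best$i]] <- list(members = c(ci$members, cj$members),
                               index = n + step, ref = step)
    clusters[[best$j]] <- NULL
  }
  list(merge = merge, height = height)
}

# --- Wilcoxon oracle: enumerate group assignments, computing U by direct
# pair counting (not rank sums) --------------------------------------------
oracle_rank_sum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  u_of <- function(a_idx) {
    a <- pooled[a_idx]; b <- pooled[-a_idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U_obs <- u_of(seq_len(m))
  mu <- m * n / 2
  splits <- utils::combn(m + n, m)
  U_all <- apply(splits, 2, u_of)
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# path-parity replay of the gain/loss event log (root-to-leaf toggles)
replay_presence <- function(truth) {
  tree <- truth$tree
  ntip <- ape::Ntip(tree)
  node_name <- c(tree$tip.label,
                 sprintf("node%d", ntip + seq_len(tree$Nnode)))
  origin_node <- function(origin) {
    if (origin == "core") return(ntip + 1L)
    tips <- truth$genomes$genome_id[truth$genomes$genus_id == origin]
    idx <- match(tips, tree$tip.label)
    if (length(idx) == 1) idx else ape::getMRCA(tree, idx)
  }
  out <- matrix(FALSE, nrow(truth$tribes), ntip,
                dimnames = list(truth$tribes$tribe_id, tree$tip.label))
  for (t in seq_len(nrow(truth$tribes))) {
    tid <- truth$tribes$tribe_id[t]
    orig <- origin_node(truth$tribes$origin[t])
    ev <- truth$events[truth$events$tribe_id == tid, , drop = FALSE]
    for (leaf in seq_len(ntip)) {
      # leaf lies in origin's subtree iff the root-to-leaf path passes
      # through origin; outside that subtree the tribe is absent by origin
      rootpath <- ape::nodepath(tree, ntip + 1L, leaf)
      if (!(orig %in% rootpath)) next
      seg <- rootpath[seq(match(orig, rootpath), length(rootpath))]
      toggles <- sum(ev$branch %in% node_name[seg[-1]])
      out[t, leaf] <- xor(TRUE, toggles %% 2 == 1)
    }
  }
  out
}
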