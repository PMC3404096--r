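test_that("empty hit table yields one singleton tribe per gene", {
  genes <- toy_genes(sprintf("g%d", 1:5), sprintf("G%d", c(1, 1, 2, 2, 3)))
  tribes <- build_within_genus_tribes(toy_hits(character(0), character(0),
                                               numeric(0)), genes, "genusA")
  expect_equal(nrow(tribes), 5L)
  expect_equal(length(unique(tribes$tribe_id)), 5L)
  expect_setequal(tribes$gene_id, genes$gene_id)
})

test_that("RBH chains merge into one tribe; isolated genes stay singletons", {
  # 3 genomes; RBH edges g1-g2 and g2-g3; g4 isolated
  genes <- toy_genes(sprintf("g%d", 1:4), sprintf("G%d", c(1, 2, 3, 3)))
  hits <- toy_hits(c("g1", "g2", "g2", "g3"),
                   c("g2", "g1", "g3", "g2"),
                   bitscore = c(100, 100, 90, 90))
  tribes <- build_within_genus_tribes(hits, genes, "genusA")
  expect_equal(canonical_membership(tribes),
               list(c("g1", "g2", "g3"), "g4"))
})

test_that("best-hit rank breaks ties by E-value then subject id", {
  # g1's hits into genome 2: equal bit scores, e-value decides; then lex id
  genes <- toy_genes(c("g1", "h1", "h2", "h3"), c("G1", "G2", "G2", "G2"))
  hits <- rbind(
    toy_hits("g1", "h2", 100, evalue = 1e-20),
    toy_hits("g1", "h1", 100, evalue = 1e-10),
    toy_hits("h2", "g1", 100, evalue = 1e-20))
  tribes <- build_within_genus_tribes(hits, genes, "genusA")
  expect_equal(canonical_membership(tribes),
               list(c("g1", "h2"), "h1", "h3"))
})

test_that("duplicate symmetric hits give the same partition as single edges", {
  genes <- toy_genes(c("a", "b"), c("G1", "G2"))
  once <- toy_hits(c("a", "b"), c("b", "a"), c(50, 50))
  twice <- rbind(once, once)
  t1 <- build_within_genus_tribes(once, genes, "genusA")
  t2 <- build_within_genus_tribes(twice, genes, "genusA")
  expect_equal(canonical_membership(t1), canonical_membership(t2))
})

test_that("self-hits are dropped and unknown genes are an error", {
  genes <- toy_genes(c("a", "b"), c("G1", "G2"))
  with_self <- rbind(toy_hits("a", "a", 999), toy_hits(c("a", "b"),
                                                       c("b", "a"), c(50, 50)))
  expect_equal(length(unique(
    build_within_genus_tribes(with_self, genes, "genusA")$tribe_id)), 1L)
  expect_error(build_within_genus_tribes(toy_hits("a", "nope", 10), genes,
                                         "genusA"), "unknown")
})

test_that("RBH partition equals a brute-force union-find oracle", {
  # random small instances: the package's per-genome-pair best-hit + RBH +
  # components must match an oracle that enumerates RBH edges directly
  for (seed in 1:5) {
    set.seed(seed)
    n_genomes <- 3
    genes_per <- 4
    ids <- sprintf("G%d_x%d", rep(1:n_genomes, each = genes_per),
                   rep(1:genes_per, n_genomes))
    genome <- rep(sprintf("G%d", 1:n_genomes), each = genes_per)
    genes <- toy_genes(ids, genome)
    # random sparse hit table with distinct scores (no tie ambiguity)
    pairs <- expand.grid(q = ids, s = ids, stringsAsFactors = FALSE)
    pairs <- pairs[genome[match(pairs$q, ids)] != genome[match(pairs$s, ids)], ]
    pairs <- pairs[sample(nrow(pairs), nrow(pairs) %/% 2), ]
    hits <- toy_hits(pairs$q, pairs$s,
                     bitscore = sample(1000, nrow(pairs)))
    tribes <- build_within_genus_tribes(hits, genes, "genusA")

    # oracle: best hit per (query, subject genome) by max score scan
    best <- list()
    for (q in unique(hits$query_id)) {
      for (sg in unique(genome)) {
        rows <- hits[hits$query_id == q &
                       genome[match(hits$subject_id, ids)] == sg, ]
        if (nrow(rows) > 0)
          best[[paste(q, sg)]] <- rows$subject_id[which.max(rows$bitscore)]
      }
    }
    edge_of <- function(a, b) {
      ga <- genome[match(a, ids)]; gb <- genome[match(b, ids)]
      identical(best[[paste(a, gb)]], b) && identical(best[[paste(b, ga)]], a)
    }
    comp <- setNames(seq_along(ids), ids)
    for (a in ids) for (b in ids) {
      if (a < b && edge_of(a, b)) {
        old <- comp[b]; comp[comp == old] <- comp[a]
      }
    }
    oracle_sets <- unname(lapply(split(ids, comp), sort))
    oracle_sets <- oracle_sets[order(vapply(oracle_sets, `[`, character(1), 1))]
    expect_equal(canonical_membership(tribes), oracle_sets, info = seed)
  }
})

test_that("pair score is the arithmetic mean of pooled cross-hit bit scores", {
  ta <- data.frame(tribe_id = "A1", gene_id = c("a1", "a2"), scope = "gA",
                   stringsAsFactors = FALSE)
  tb <- data.frame(tribe_id = "B1", gene_id = c("b1", "b2"), scope = "gB",
                   stringsAsFactors = FALSE)
  cross <- toy_hits(c("a1", "b1", "a2", "b2"), c("b1", "a1", "b2", "a2"),
                    bitscore = c(100, 110, 90, 100))
  res <- join_tribes(ta, tb, cross)
  expect_equal(res$joins$pair_score, 100)
  expect_equal(unique(res$tribes$tribe_id), "joint00001")
  expect_equal(unique(res$tribes$scope), "joined")
})

test_that("RBH join fails when best partners disagree", {
  ta <- data.frame(tribe_id = c("A1", "A2"), gene_id = c("a1", "a2"),
                   scope = "gA", stringsAsFactors = FALSE)
  tb <- data.frame(tribe_id = "B1", gene_id = "b1", scope = "gB",
                   stringsAsFactors = FALSE)
  # A1's best is B1, but B1 prefers A2
  cross <- toy_hits(c("a1", "a2"), c("b1", "b1"), bitscore = c(50, 80))
  res <- join_tribes(ta, tb, cross)
  expect_equal(res$joins$tribe_a, "A2")
  expect_equal(res$joins$tribe_b, "B1")
  expect_equal(sum(res$tribes$scope == "joined"), 2L)  # a2 + b1 members
  expect_true("A1" %in% res$tribes$tribe_id)           # A1 passes through
})

test_that("joining with no cross hits is the disjoint union", {
  ta <- data.frame(tribe_id = "A1", gene_id = "a1", scope = "gA",
                   stringsAsFactors = FALSE)
  tb <- data.frame(tribe_id = "B1", gene_id = "b1", scope = "gB",
                   stringsAsFactors = FALSE)
  res <- join_tribes(ta, tb, toy_hits(character(0), character(0), numeric(0)))
  expect_equal(nrow(res$joins), 0L)
  expect_setequal(res$tribes$tribe_id, c("A1", "B1"))
})

test_that("a cross hit internal to one genus is an error", {
  ta <- data.frame(tribe_id = c("A1", "A2"), gene_id = c("a1", "a2"),
                   scope = "gA", stringsAsFactors = FALSE)
  tb <- data.frame(tribe_id = "B1", gene_id = "b1", scope = "gB",
                   stringsAsFactors = FALSE)
  expect_error(join_tribes(ta, tb, toy_hits("a1", "a2", 10)), "internal")
})

test_that("join acceptance equals the brute-force pair-score matrix oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    na <- 4; nb <- 3; per <- 2
    ga <- sprintf("a%d_%d", rep(1:na, each = per), rep(1:per, na))
    gb <- sprintf("b%d_%d", rep(1:nb, each = per), rep(1:per, nb))
    ta <- data.frame(tribe_id = sprintf("A%d", rep(1:na, each = per)),
                     gene_id = ga, scope = "gA", stringsAsFactors = FALSE)
    tb <- data.frame(tribe_id = sprintf("B%d", rep(1:nb, each = per)),
                     gene_id = gb, scope = "gB", stringsAsFactors = FALSE)
    pairs <- expand.grid(q = ga, s = gb, stringsAsFactors = FALSE)
    pairs <- pairs[sample(nrow(pairs), 14), ]
    cross <- toy_hits(pairs$q, pairs$s, bitscore = sample(500, 14))
    res <- join_tribes(ta, tb, cross)

    # oracle: dense pair-score matrix, then mutual-argmax scan
    S <- matrix(NA_real_, na, nb, dimnames = list(sprintf("A%d", 1:na),
                                                  sprintf("B%d", 1:nb)))
    for (i in 1:na) for (j in 1:nb) {
      rows <- cross[cross$query_id %in% ga[(i - 1) * per + 1:per] &
                      cross$subject_id %in% gb[(j - 1) * per + 1:per], ]
      if (nrow(rows) > 0) S[i, j] <- mean(rows$bitscore)
    }
    expected <- character(0)
    for (i in 1:na) for (j in 1:nb) {
      if (is.na(S[i, j])) next
      if (S[i, j] == max(S[i, ], na.rm = TRUE) &&
          S[i, j] == max(S[, j], na.rm = TRUE))
        expected <- c(expected, paste(rownames(S)[i], colnames(S)[j]))
    }
    got <- paste(res$joins$tribe_a, res$joins$tribe_b)
    expect_setequal(got, expected)

    # symmetry: swapping the genera accepts the same pairs
    swapped <- join_tribes(tb, ta, cross)
    expect_setequal(paste(swapped$joins$tribe_b, swapped$joins$tribe_a),
                    expected)

    # row-order invariance
    shuf <- cross[sample(nrow(cross)), ]
    expect_equal(join_tribes(ta, tb, shuf)$joins, res$joins)

    # gene conservation
    expect_setequal(res$tribes$gene_id, c(ga, gb))
  }
})

test_that("noiseless synthetic data: recovered tribes equal truth membership", {
  p <- noiseless_params(seed = 17L)
  truth <- generate_pangenome(p)
  ann <- emit_annotations(truth, p)
  hits <- emit_similarity_hits(truth, p)
  res <- run_tribe_pipeline(ann, hits, emit_profile_hits(truth, p))
  expect_equal(canonical_membership(res$joined$tribes),
               canonical_membership(data.frame(tribe_id = truth$genes$tribe_id,
                                               gene_id = truth$genes$gene_id)))
  # total gene count conserved through construction and joining
  expect_equal(nrow(res$joined$tribes), nrow(truth$genes))
})

test_that("consensus function is the modal product, ties lexicographic", {
  genes <- toy_genes(sprintf("g%d", 1:3), "G1",
                     product = c("PCNA", "PCNA", "hypothetical protein"))
  expect_equal(assign_tribe_function(c("g1", "g2", "g3"), genes), "PCNA")
  expect_equal(assign_tribe_function(c("g1", "g2"), genes), "PCNA")
  tie <- toy_genes(c("x", "y"), "G1", product = c("B", "A"))
  expect_equal(assign_tribe_function(c("x", "y"), tie), "A")
  expect_error(assign_tribe_function(c("g1", "ghost"), genes), "ghost")
})
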