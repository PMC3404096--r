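ph <- function(gene, profile, evalue, cov_gene = 0.9, cov_profile = 0.9) {
  data.frame(gene_id = gene, profile_id = profile, evalue = evalue,
             cov_gene = cov_gene, cov_profile = cov_profile,
             stringsAsFactors = FALSE)
}

test_that("profile-hit filter is strict on both boundaries", {
  hits <- rbind(
    ph("keep", "p", 5e-5, 0.9, 0.9),        # passes all three
    ph("e_at_bound", "p", 1e-4, 0.9, 0.9),  # E-value not strictly below
    ph("cov_at_bound", "p", 1e-6, 0.80, 0.95),  # gene coverage not above
    ph("profcov_at_bound", "p", 1e-6, 0.95, 0.80))
  kept <- filter_profile_hits(hits)
  expect_equal(kept$gene_id, "keep")
})

test_that("relaxing thresholds never removes a kept row (monotone filter)", {
  set.seed(42)
  hits <- ph(sprintf("g%d", 1:300), "p",
             evalue = 10^-runif(300, 0, 8),
             cov_gene = runif(300, 0.5, 1), cov_profile = runif(300, 0.5, 1))
  base <- filter_profile_hits(hits)
  for (e_max in c(1e-3, 1e-2)) {
    for (cov_min in c(0.7, 0.6)) {
      relaxed <- filter_profile_hits(hits, e_max = e_max, cov_min = cov_min)
      expect_true(all(base$gene_id %in% relaxed$gene_id))
    }
  }
})

test_that("best-profile assignment picks minimal E-value with stated tie-breaks", {
  hits <- rbind(ph("g1", "P1", 1e-6), ph("g1", "P2", 1e-5))
  expect_equal(assign_best_profile(hits)$profile_id, "P1")
  expect_equal(assign_best_profile(ph("g2", "P9", 1e-3))$profile_id, "P9")
  tie <- rbind(ph("g3", "Phi", 1e-6, 0.9, 0.95),
               ph("g3", "Plo", 1e-6, 0.9, 0.90))
  expect_equal(assign_best_profile(tie)$profile_id, "Phi")
  # full tie falls through to lexicographic profile id
  tie2 <- rbind(ph("g4", "Pb", 1e-6), ph("g4", "Pa", 1e-6))
  expect_equal(assign_best_profile(tie2)$profile_id, "Pa")
})

test_that("assignment is independent of input row order", {
  set.seed(7)
  hits <- ph(sample(sprintf("g%d", 1:40), 200, replace = TRUE),
             sample(sprintf("p%d", 1:15), 200, replace = TRUE),
             evalue = 10^-runif(200, 1, 9),
             cov_gene = runif(200, 0.81, 1), cov_profile = runif(200, 0.81, 1))
  hits <- hits[!duplicated(hits[c("gene_id", "profile_id")]), ]
  a <- assign_best_profile(hits)
  b <- assign_best_profile(hits[sample(nrow(hits)), ])
  expect_equal(a, b)
})

test_that("presence matrix entries match brute-force tabulation", {
  assignments <- data.frame(
    gene_id = c("x1", "x2", "y1", "y2", "y3"),
    profile_id = c("t1", "t2", "t1", "t1", "t3"),
    stringsAsFactors = FALSE)
  gene_genomes <- c(x1 = "G1", x2 = "G1", y1 = "G2", y2 = "G2", y3 = "G2")
  m <- build_presence_matrix(assignments, c("t1", "t2", "t3", "t4"),
                             c("G1", "G2"), gene_genomes)
  expected <- matrix(0L, 4, 2, dimnames = list(c("t1", "t2", "t3", "t4"),
                                               c("G1", "G2")))
  for (i in seq_len(nrow(assignments))) {
    expected[assignments$profile_id[i],
             gene_genomes[assignments$gene_id[i]]] <- 1L
  }
  expect_identical(m, expected)
  # two genes of one genome in one tribe -> still 1 (binary, not counts)
  expect_equal(m["t1", "G2"], 1L)
  # empty tribe keeps its all-zero row
  expect_equal(unname(m["t4", ]), c(0L, 0L))
})

test_that("all-zero matrix of the requested shape when nothing is assigned", {
  m <- build_presence_matrix(
    data.frame(gene_id = character(), profile_id = character()),
    c("t1", "t2"), c("G1", "G2", "G3"), character(0))
  expect_equal(dim(m), c(2L, 3L))
  expect_true(all(m == 0L))
  expect_error(build_presence_matrix(
    data.frame(gene_id = "g", profile_id = "nope"), c("t1"), c("G1"),
    c(g = "G1")), "unknown tribe")
})

test_that("hand-worked clustering example: merge heights 1 then 3", {
  m <- matrix(c(0, 0, 0, 0, 0, 1, 1, 1, 1), 3, byrow = TRUE,
              dimnames = list(c("r1", "r2", "r3"), c("c1", "c2", "c3")))
  d <- cluster_matrix(m, "rows")
  expect_equal(d$height, c(1, 3))
  expect_equal(d$merge[1, ], c(-1L, -2L))  # the distance-1 pair merges first
  expect_identical(sort(d$order), 1:3)
})

test_that("identical rows merge at height zero", {
  m <- matrix(c(1, 0, 1, 1, 0, 1, 0, 1, 1), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  d <- cluster_matrix(m, "rows")
  expect_equal(d$height[1], 0)
  expect_equal(d$merge[1, ], c(-1L, -2L))
})

test_that("single-item axis is an error", {
  m <- matrix(0, 1, 3, dimnames = list("only", c("a", "b", "c")))
  expect_error(cluster_matrix(m, "rows"), "single-item")
})

test_that("agglomeration matches the naive O(n^3) oracle on random matrices", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(rbinom(72, 1, 0.5), 12, 6,
                dimnames = list(sprintf("r%02d", 1:12), sprintf("c%d", 1:6)))
    got <- cluster_matrix(m, "rows")
    want <- oracle_complete_linkage(m)
    expect_identical(got$merge, want$merge, info = seed)
    expect_equal(got$height, want$height, info = seed)
    expect_false(is.unsorted(got$height))
  }
})

test_that("tie-free instances agree with stats::hclust", {
  set.seed(123)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(sprintf("r%02d", 1:10), sprintf("c%d", 1:6)))
  got <- cluster_matrix(m, "rows")
  ref <- stats::hclust(dist(m, method = "manhattan"), method = "complete")
  expect_equal(sort(got$height), sort(ref$height))
  # identical partitions at every merge level
  gh <- as.hclust(got)
  for (k in 2:5) {
    a <- stats::cutree(gh, k)
    b <- stats::cutree(ref, k)
    expect_equal(length(unique(paste(a, b))), k, info = k)
  }
})

test_that("noiseless pipeline reproduces the truth matrix entry-for-entry", {
  p <- noiseless_params(seed = 29L)
  truth <- generate_pangenome(p)
  res <- run_tribe_pipeline(emit_annotations(truth, p),
                            emit_similarity_hits(truth, p),
                            emit_profile_hits(truth, p),
                            tribe_ids = rownames(truth$presence))
  tm <- truth_presence_matrix(truth)
  expect_identical(res$matrix[rownames(tm), colnames(tm)], tm)
})
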