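# The generator is first-class pipeline code: its truth object is what every
# downstream stage is validated against, so its own contracts get tested.

test_that("parameter validation names the offending field", {
  expect_error(sim_params(loss_rate = 1.5), "loss_rate")
  expect_error(sim_params(clade_loss_boost = 0.5), "clade_loss_boost")
  expect_error(sim_params(n_core_tribes = -1), "n_core_tribes")
  expect_error(sim_params(cog_effect = list(ZZ = c(genusA = 0.1, genusB = 0.1))),
               "cog_effect")
  expect_error(sim_params(cog_effect = list(T = c(genusA = 0.5, genusB = 0.5)),
                          baseline_cog_fraction = 0.4), "cog_effect")
})

test_that("no-flux limit: every genome carries all core tribes", {
  p <- small_params(n_core_tribes = 100L,
                    n_genus_tribes = c(genusA = 0L, genusB = 0L),
                    loss_rate = 0, gain_rate = 0)
  truth <- generate_pangenome(p)
  expect_equal(nrow(truth$tribes), 100L)
  expect_true(all(truth$presence))
  expect_equal(nrow(truth$events), 0L)
  # one gene per (genome, tribe)
  expect_equal(nrow(truth$genes), 100L * 9L)
  expect_false(anyDuplicated(truth$genes$gene_id) > 0)
})

test_that("same seed gives identical event logs and byte-identical tables", {
  p <- small_params(seed = 42L)
  t1 <- generate_pangenome(p)
  t2 <- generate_pangenome(p)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$presence, t2$presence)
  d1 <- file.path(tempdir(), "pg1"); d2 <- file.path(tempdir(), "pg2")
  write_pangenome(t1, p, d1)
  write_pangenome(t2, p, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  t3 <- generate_pangenome(small_params(seed = 43L))
  expect_false(identical(t1$presence, t3$presence))
})

test_that("designated clade loses tribes at the boosted rate", {
  # compare the clade stem branch against the depth-matched background stem
  # in the other genus: both inherit the same attrition history, so the
  # expected per-branch loss ratio is exactly the boost factor, and stem
  # losses approximate the no-attrition closed form boost * rate * n_tribes
  n_seeds <- 200
  p0 <- small_params(n_core_tribes = 200L,
                     n_genus_tribes = c(genusA = 0L, genusB = 0L),
                     loss_rate = 0.02, gain_rate = 0, clade_loss_boost = 10)
  tr <- generate_pangenome(p0)
  ntip <- ape::Ntip(tr$tree)
  clade_stem <- sprintf("node%d",
                        ape::getMRCA(tr$tree, match(p0$clade_genomes,
                                                    tr$tree$tip.label)))
  bg_stem <- sprintf("node%d",
                     ape::getMRCA(tr$tree, match(c("genusB_03", "genusB_04"),
                                                 tr$tree$tip.label)))
  clade_losses <- bg_losses <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    tt <- generate_pangenome(small_params(
      n_core_tribes = 200L, n_genus_tribes = c(genusA = 0L, genusB = 0L),
      loss_rate = 0.02, gain_rate = 0, clade_loss_boost = 10,
      seed = 1000L + s))
    ev <- tt$events[tt$events$event == "loss", ]
    clade_losses[s] <- sum(ev$branch == clade_stem)
    bg_losses[s] <- sum(ev$branch == bg_stem)
  }
  expect_equal(mean(clade_losses) / mean(bg_losses), 10, tolerance = 0.15)
  expect_equal(mean(clade_losses), 10 * 0.02 * 200, tolerance = 0.10)
})

test_that("presence equals origin presence XOR path parity of the event log", {
  for (seed in c(3L, 11L)) {
    truth <- generate_pangenome(small_params(
      seed = seed, loss_rate = 0.08, gain_rate = 0.05, clade_loss_boost = 4))
    expect_identical(unname(truth$presence),
                     unname(replay_presence(truth)[rownames(truth$presence),
                                                   colnames(truth$presence)]))
  }
})

test_that("similarity hits: within-tribe pair counts and score separation", {
  p <- noiseless_params(n_core_tribes = 1L,
                        n_genus_tribes = c(genusA = 0L, genusB = 0L),
                        loss_rate = 0, gain_rate = 0)
  truth <- generate_pangenome(p)
  hits <- emit_similarity_hits(truth, p)
  k <- nrow(truth$genes)
  expect_equal(nrow(hits), k * (k - 1))  # all directed pairs, no self-hits
  expect_false(any(hits$query_id == hits$subject_id))

  p2 <- small_params(score_noise_sd = 0, seed = 5L)
  t2 <- generate_pangenome(p2)
  h2 <- emit_similarity_hits(t2, p2)
  tribe_of <- setNames(t2$genes$tribe_id, t2$genes$gene_id)
  within <- tribe_of[h2$query_id] == tribe_of[h2$subject_id]
  expect_gt(sum(!within), 0)  # noise pairs present at the default rate
  expect_gt(min(h2$bitscore[within]), max(h2$bitscore[!within]))
  expect_true(all(h2$q_cov >= 0 & h2$q_cov <= 1))
  expect_true(all(h2$evalue >= 0))
  # E-value is a monotone transform of bit score
  expect_false(is.unsorted(rev(h2$evalue[order(h2$bitscore)])))
})

test_that("empty truth yields empty hit tables", {
  p <- small_params(n_core_tribes = 4L,
                    n_genus_tribes = c(genusA = 0L, genusB = 0L),
                    loss_rate = 0.999999, gain_rate = 0, clade_loss_boost = 1)
  truth <- generate_pangenome(p)
  truth$genes <- truth$genes[0, ]
  expect_equal(nrow(emit_similarity_hits(truth, p)), 0L)
  expect_equal(nrow(emit_profile_hits(truth, p)), 0L)
  expect_equal(nrow(emit_annotations(truth, p)), 0L)
})

test_that("profile hits: true members pass thresholds, each gene maps to one profile", {
  p <- small_params(seed = 9L)
  truth <- generate_pangenome(p)
  prof <- emit_profile_hits(truth, p)
  true_rows <- prof$profile_id ==
    truth$genes$tribe_id[match(prof$gene_id, truth$genes$gene_id)]
  expect_true(all(prof$evalue[true_rows] < 1e-6))
  expect_true(all(prof$cov_gene[true_rows] > 0.9 &
                    prof$cov_profile[true_rows] > 0.9))
  expect_gt(sum(!true_rows), 0)  # decoys emitted
  # decoys span the filter thresholds on both sides
  decoys <- prof[!true_rows, ]
  expect_gt(sum(decoys$evalue >= 1e-4), 0)
  expect_gt(sum(decoys$evalue < 1e-4), 0)
  # brute-force: best-hit assignment leaves each gene with at most 1 profile
  assigned <- assign_best_profile(filter_profile_hits(prof))
  expect_false(anyDuplicated(assigned$gene_id) > 0)
})

test_that("injected decoy below the coverage bound is absent after filtering", {
  p <- small_params(seed = 13L)
  truth <- generate_pangenome(p)
  prof <- emit_profile_hits(truth, p)
  decoy <- data.frame(gene_id = truth$genes$gene_id[1],
                      profile_id = "core00002", evalue = 1e-12,
                      cov_gene = 0.5, cov_profile = 0.95,
                      stringsAsFactors = FALSE)
  kept <- filter_profile_hits(rbind(prof, decoy))
  expect_equal(nrow(kept[kept$gene_id == decoy$gene_id &
                           kept$profile_id == decoy$profile_id &
                           kept$cov_gene == 0.5, ]), 0L)
})

test_that("realized COG fractions match the per-genus targets", {
  n_seeds <- 100
  frac <- matrix(NA_real_, n_seeds, 2,
                 dimnames = list(NULL, c("genusA", "genusB")))
  for (s in seq_len(n_seeds)) {
    p <- small_params(n_core_tribes = 80L,
                      n_genus_tribes = c(genusA = 20L, genusB = 20L),
                      seed = 2000L + s)
    truth <- generate_pangenome(p)
    ann <- emit_annotations(truth, p)
    has_t <- grepl("T", ann$cog, fixed = TRUE)
    for (g in c("genusA", "genusB"))
      frac[s, g] <- sum(has_t & ann$genus_id == g) / sum(ann$genus_id == g)
  }
  expect_lt(abs(mean(frac[, "genusA"]) - 0.030), 0.002)
  expect_lt(abs(mean(frac[, "genusB"]) - 0.042), 0.002)
})

test_that("controlled product vocabulary gives known screen counts", {
  p <- small_params(seed = 21L)
  truth <- generate_pangenome(p)
  truth$tribes$function_label[1] <- "cellulase family protein"
  ann <- emit_annotations(truth, p)
  target <- truth$tribes$tribe_id[1]
  expected <- table(factor(ann$genome_id[truth$genes$tribe_id == target],
                           levels = unique(ann$genome_id)))
  counts <- screen_by_annotation(ann, "cellulase")
  cellulase_tribes <- truth$tribes$tribe_id[
    truth$tribes$function_label == "cellulase family protein"]
  manual <- table(factor(
    ann$genome_id[truth$genes$tribe_id %in% cellulase_tribes],
    levels = counts$genome_id))
  expect_equal(counts$cellulase, as.integer(manual))
})
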