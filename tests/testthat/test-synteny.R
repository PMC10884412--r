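test_that("homology filter applies the published thresholds exactly", {
  hits <- data.frame(
    query = paste0("q", 1:4), subject = paste0("s", 1:4),
    identity = c(29.9, 30, 100, 90),
    evalue = c(1e-50, 1e-50, 0, 1e-10),
    coverage_q = c(1, 1, 1, 1), coverage_s = c(1, 0.29, 1, 1),
    bitscore = 100, stringsAsFactors = FALSE)
  kept <- filter_homology_hits(hits)
  # 29.9% identity out; 29% subject coverage out; exact 1e-10 out
  expect_equal(kept$query, "q3")
})

test_that("blocks need at least five shared genes", {
  genes_a <- toy_genes(10, "A")
  genes_b <- toy_genes(10, "B", prefix = "B")
  hits4 <- toy_hits(paste0("A", 1:4), paste0("B", 1:4))
  expect_length(chain_collinear_blocks(hits4, genes_a, genes_b), 0L)
  hits5 <- toy_hits(paste0("A", 1:5), paste0("B", 1:5))
  bl <- chain_collinear_blocks(hits5, genes_a, genes_b)
  expect_length(bl, 1L)
  expect_equal(bl[[1]]$orientation, "same")
  expect_equal(bl[[1]]$n_anchors, 5L)
})

test_that("inverted collinearity is chained in reverse orientation", {
  genes_a <- toy_genes(8, "A")
  genes_b <- toy_genes(8, "B", prefix = "B")
  hits <- toy_hits(paste0("A", 1:6), paste0("B", 6:1))
  bl <- chain_collinear_blocks(hits, genes_a, genes_b)
  expect_length(bl, 1L)
  expect_equal(bl[[1]]$orientation, "inverted")
  expect_equal(bl[[1]]$n_anchors, 6L)
})

test_that("block anchors are strictly monotone in both genomes", {
  cfg <- quick_config(seed = 13)
  sim <- simulate_wgt_genomes(cfg)
  hits <- filter_homology_hits(
    sim_homology_hits(sim$descendants$spA, sim$descendants$spA, seed = 13))
  bl <- chain_collinear_blocks(hits, sim$descendants$spA,
                               sim$descendants$spA)
  expect_gt(length(bl), 0L)
  for (b in bl) {
    expect_true(all(diff(b$anchors$rank_a) > 0))
    d <- diff(b$anchors$rank_b)
    expect_true(all(d > 0) || all(d < 0))
  }
})

test_that("DP chaining equals exhaustive enumeration on random toys", {
  set.seed(71)
  for (trial in 1:120) {
    n <- sample(6:12, 1)
    rb <- sample.int(n)
    genes_a <- toy_genes(n, "A")
    genes_b <- toy_genes(n, "B", prefix = "B")
    hits <- toy_hits(paste0("A", 1:n), paste0("B", rb),
                     bitscore = runif(n, 100, 500))
    bl <- chain_collinear_blocks(hits, genes_a, genes_b, min_genes = 4L,
                                 max_gap = 8L, gap_penalty = 0.5,
                                 collapse_tandem = FALSE)
    anc <- data.frame(ra = 1:n, rb = rb, score = hits$bitscore / 100)
    oracle <- brute_block_set(anc, 4L, 8L, 0.5)
    expect_equal(length(bl), length(oracle))
    for (k in seq_along(bl)) {
      expect_equal(sort(bl[[k]]$anchors$rank_a), sort(oracle[[k]]$ra))
      expect_equal(bl[[k]]$score, oracle[[k]]$score, tolerance = 1e-9)
    }
  }
})

test_that("tandem duplicates collapse to the best hit before chaining", {
  genes_a <- toy_genes(8, "A")
  genes_b <- toy_genes(8, "B", prefix = "B")
  hits <- rbind(toy_hits(paste0("A", 1:6), paste0("B", 1:6)),
                # A7 is a tandem copy next to A6, hitting the same B6
                toy_hits("A7", "B6", bitscore = 500))
  bl <- chain_collinear_blocks(hits, genes_a, genes_b)
  expect_length(bl, 1L)
  expect_false(all(c("A6", "A7") %in% bl[[1]]$anchors$gene_a))
})

test_that("synteny depth against the ancestor is modal 3 without loss", {
  cfg <- quick_config(seed = 17, n_anc_genes = 400, loss_prob = 0,
                      inv_rate = 0, fus_rate = 0, fis_rate = 0)
  sim <- simulate_wgt_genomes(cfg)
  hits <- filter_homology_hits(
    sim_homology_hits(sim$ancestor, sim$descendants$spA, seed = 17))
  bl <- chain_collinear_blocks(hits, sim$ancestor, sim$descendants$spA)
  depth <- synteny_depth_ratio(bl, sim$ancestor)
  expect_equal(depth$modal_depth, 3L)
})

test_that("depth histogram matches the truth-derived depth under loss", {
  cfg <- quick_config(seed = 19, n_anc_genes = 400, loss_prob = 0.5,
                      inv_rate = 0, fus_rate = 0, fis_rate = 0)
  sim <- simulate_wgt_genomes(cfg)
  hits <- filter_homology_hits(
    sim_homology_hits(sim$ancestor, sim$descendants$spA, seed = 19))
  bl <- chain_collinear_blocks(hits, sim$ancestor, sim$descendants$spA,
                               max_gap = 100L, gap_penalty = 0.01)
  depth <- synteny_depth_ratio(bl, sim$ancestor)
  # truth oracle: per subgenome, the covered range on each ancestral
  # chromosome spans the surviving copies; depth = covering subgenomes
  anc <- sim$ancestor
  surv <- sim$truth$survival$spA
  truth_depth <- setNames(integer(nrow(anc)), anc$gene_id)
  for (k in 1:3) {
    for (ch in unique(anc$chromosome)) {
      on_ch <- anc$chromosome == ch
      has <- on_ch & surv[, k]
      if (!any(has)) next
      rng <- range(anc$rank[has])
      cov <- on_ch & anc$rank >= rng[1] & anc$rank <= rng[2]
      truth_depth[cov] <- truth_depth[cov] + 1L
    }
  }
  expect_equal(depth$depth, truth_depth)
})

test_that("ploidy ladder arithmetic matches the printed expectations", {
  expect_identical(expected_ploidy_ladder(7, c(3, 2, 2, 2)), 168L)
  expect_identical(expected_ploidy_ladder(8, 3), 24L)
  expect_identical(expected_ploidy_ladder(13), 13L)
  expect_error(expected_ploidy_ladder(0), "n_base")
  expect_error(expected_ploidy_ladder(7, c(3, 0)), "multipliers")
  expect_error(expected_ploidy_ladder(2.5), "n_base")
})

test_that("rearrangement counting matches hand enumeration", {
  identity_map <- list(
    d1 = data.frame(anc_chrom = "a1", sign = 1L),
    d2 = data.frame(anc_chrom = "a2", sign = 1L))
  ev <- count_rearrangement_events(identity_map, c("a1", "a2"))
  expect_equal(ev, list(fusion = 0L, fission = 0L,
                        inversion_breakpoints = 0L))

  fused <- list(d1 = data.frame(anc_chrom = c("a1", "a2"),
                                sign = c(1L, 1L)))
  expect_equal(count_rearrangement_events(fused, c("a1", "a2"))$fusion, 1L)

  # hand-enumerated 3-chromosome toy:
  # d1 = a1+ a1- a2+  -> 1 fusion, 1 inversion breakpoint
  # d2 = a2+           (a2 split over d1, d2 -> 1 fission)
  # d3 = a3+ a3+ a1+  -> 1 fusion, a1 split -> 1 fission, no sign change
  toy <- list(
    d1 = data.frame(anc_chrom = c("a1", "a1", "a2"), sign = c(1L, -1L, 1L)),
    d2 = data.frame(anc_chrom = "a2", sign = 1L),
    d3 = data.frame(anc_chrom = c("a3", "a3", "a1"), sign = c(1L, 1L, 1L)))
  ev <- count_rearrangement_events(toy, c("a1", "a2", "a3"))
  expect_equal(ev$fusion, 2L)
  expect_equal(ev$fission, 2L)
  expect_equal(ev$inversion_breakpoints, 1L)

  expect_error(count_rearrangement_events(fused, "a1"), "unknown ancestral")
})
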