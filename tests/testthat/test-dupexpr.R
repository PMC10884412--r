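test_that("the exact conditional test matches full enumeration", {
  expect_equal(pair_exact_test(5, 5, 0.5), 1.0)
  expect_equal(pair_exact_test(10, 0, 0.5), 2 * 0.5^10)
  for (n in c(3, 7, 12, 20)) {
    for (k in 0:n) {
      for (p0 in c(0.3, 0.5, 0.62)) {
        expect_equal(pair_exact_test(k, n - k, p0),
                     enumerate_binom_p(k, n, p0), tolerance = 1e-12,
                     info = sprintf("k=%d n=%d p0=%g", k, n, p0))
      }
    }
  }
})

test_that("the test is symmetric at p0 = 0.5 and validates input", {
  for (ab in list(c(3, 9), c(0, 4), c(7, 7))) {
    expect_equal(pair_exact_test(ab[1], ab[2], 0.5),
                 pair_exact_test(ab[2], ab[1], 0.5))
  }
  expect_error(pair_exact_test(0, 0, 0.5), "positive total")
  expect_error(pair_exact_test(3, 4, 0), "null_p0")
  expect_error(pair_exact_test(3, 4, 1), "null_p0")
})

make_cm <- function(counts, tissues = 1L, reps = ncol(counts),
                    pairs = NULL) {
  samples <- expand.grid(replicate = seq_len(reps),
                         tissue = paste0("t", seq_len(tissues)),
                         stringsAsFactors = FALSE)[, c(2, 1)]
  names(samples) <- c("tissue", "replicate")
  samples$sample <- paste0(samples$tissue, ".rep", samples$replicate)
  colnames(counts) <- samples$sample
  out <- list(counts = counts, samples = samples, pairs = pairs,
              truth_degp = NULL)
  class(out) <- "count_matrix"
  out
}

test_that("identical counts are never called divergent", {
  counts <- matrix(50L, nrow = 2, ncol = 3,
                   dimnames = list(c("g1", "g2"), NULL))
  cm <- make_cm(counts, pairs = data.frame(gene_a = "g1", gene_b = "g2"))
  tests <- test_duplicate_groups(cm)
  expect_false(any(tests$consistent_significant))
})

test_that("three-copy groups contribute exactly three pairwise tests", {
  groups <- data.frame(group_id = "rg1", species = "sp", copy_class = 3L,
                       members = "g1;g2;g3", stringsAsFactors = FALSE)
  pairs <- groups_to_pairs(groups)
  expect_equal(nrow(pairs), 3L)
  counts <- matrix(c(100L, 100L, 800L), nrow = 3, ncol = 3,
                   dimnames = list(c("g1", "g2", "g3"), NULL))
  cm <- make_cm(counts, pairs = pairs)
  tests <- test_duplicate_groups(cm)
  expect_equal(nrow(tests), 9L)  # 3 pairs x 3 replicates
  byp <- unique(tests[, c("gene_a", "gene_b", "consistent_significant")])
  expect_equal(sum(byp$consistent_significant), 2L)  # g3 vs each of g1,g2
})

test_that("direction must be consistent across replicates", {
  counts <- matrix(c(200L, 50L, 50L, 200L, 200L, 50L), nrow = 2,
                   dimnames = list(c("g1", "g2"), NULL))
  cm <- make_cm(counts, pairs = data.frame(gene_a = "g1", gene_b = "g2"))
  tests <- test_duplicate_groups(cm)
  expect_true(all(tests$significant))
  expect_false(any(tests$consistent_significant))
})

test_that("the Bonferroni family is the tests run per tissue-replicate", {
  # two testable pairs and one all-zero pair: divisor must be 2
  counts <- matrix(c(9L, 0L, 30L, 30L, 0L, 0L), nrow = 6, ncol = 1,
                   dimnames = list(paste0("g", 1:6), NULL))
  cm <- make_cm(counts, reps = 1L,
                pairs = data.frame(gene_a = c("g1", "g3", "g5"),
                                   gene_b = c("g2", "g4", "g6")))
  tests <- test_duplicate_groups(cm)
  expect_equal(tests$corrected_p[1], min(2 * pair_exact_test(9, 0), 1))
  expect_true(is.na(tests$p_value[3]))
})

test_that("the null simulation keeps the family-wise error in check", {
  # Poisson counts match the conditional test's binomial null exactly
  fp <- 0L
  for (s in 1:8) {
    cfg <- sim_config(seed = 100 + s, n_anc_genes = 500,
                      degp_fraction = 0, nb_dispersion = 0)
    sim <- simulate_wgt_genomes(cfg)
    cm <- simulate_expression_counts(sim$truth, cfg, n_tissues = 1L)
    tests <- test_duplicate_groups(cm)
    if (any(tests$consistent_significant)) fp <- fp + 1L
  }
  expect_lte(fp / 8, 0.05 + 1e-9)
})

test_that("power increases monotonically with the expression offset", {
  fractions <- vapply(c(0.5, 1, 1.5, 2, 3), function(off) {
    cfg <- sim_config(seed = 77, n_anc_genes = 500, degp_fraction = 0.5,
                      degp_log2_offset = off)
    sim <- simulate_wgt_genomes(cfg)
    cm <- simulate_expression_counts(sim$truth, cfg, n_tissues = 1L)
    s <- summarize_degp(test_duplicate_groups(cm))
    s$per_tissue$fraction[1]
  }, numeric(1))
  expect_true(all(diff(fractions) >= 0))
  expect_lt(fractions[1], fractions[5])
})

test_that("DEGP summaries recover the simulated divergent fraction", {
  cfg <- sim_config(seed = 55, n_anc_genes = 600, degp_fraction = 0.6)
  sim <- simulate_wgt_genomes(cfg)
  cm <- simulate_expression_counts(sim$truth, cfg)
  s <- summarize_degp(test_duplicate_groups(cm))
  expect_true(all(abs(s$per_tissue$fraction - 0.6) < 0.1))
  # the cross-tissue intersection is a subset of every tissue's DEGP set
  expect_true(length(s$all_tissue_pairs) <= min(s$per_tissue$n_degp))
})

test_that("tissue-wise intersection equals hand set logic", {
  counts <- matrix(c(400L, 50L, 400L, 50L,   # t1: pair1 diverged
                     400L, 50L, 60L, 50L),   # t2: pair1 diverged, pair2 not
                   nrow = 4,
                   dimnames = list(paste0("g", 1:4), NULL))
  cm <- make_cm(counts, tissues = 2L, reps = 1L,
                pairs = data.frame(gene_a = c("g1", "g3"),
                                   gene_b = c("g2", "g4")))
  s <- summarize_degp(test_duplicate_groups(cm))
  expect_equal(s$all_tissue_pairs, "g1|g2")
})
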