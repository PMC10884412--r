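test_that("NJ recovers additive topologies and validates input", {
  d <- matrix(c(0, 2, 7, 7,
                2, 0, 7, 7,
                7, 7, 0, 2,
                7, 7, 2, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "o"),
                              c("a", "b", "c", "o")))
  tr <- build_nj_tree(d, outgroup = "o")
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
  d3 <- d[1:3, 1:3]
  expect_equal(ape::Ntip(build_nj_tree(d3, outgroup = "c")), 3L)
  d[1, 2] <- d[2, 1] <- Inf
  expect_error(build_nj_tree(d, outgroup = "o"), "non-finite")
})

test_that("NJ recovers random ultrametric topologies", {
  set.seed(53)
  for (i in 1:100) {
    tr <- ape::rcoal(6)
    tr$tip.label <- paste0("t", 1:6)
    d <- ape::cophenetic.phylo(tr)
    nj <- build_nj_tree(d, outgroup = tr$tip.label[1])
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj),
                                           ape::unroot(tr))), 0)
  }
})

test_that("duplicate-topology scenarios follow the classification rule", {
  shared <- ape::read.tree(
    text = "(((S_1:1,L_1:1):1,(S_2:1,L_2:1):1):1,O_1:3);")
  expect_equal(classify_wgt_topology(shared, c("S", "L"), "O"),
               "shared_wgt")
  lineage <- ape::read.tree(
    text = "(((S_1:1,S_2:1):1,(L_1:1,L_2:1):1):1,O_1:3);")
  expect_equal(classify_wgt_topology(lineage, c("S", "L"), "O"),
               "lineage_specific")
  missing <- ape::read.tree(text = "((S_1:1,(S_2:1,L_1:1):1):1,O_1:3);")
  expect_equal(classify_wgt_topology(missing, c("S", "L"), "O"),
               "unresolved")
  other <- ape::read.tree(
    text = "(((S_1:1,S_2:1):1,(L_1:1,L_2:1):1):1,X_1:3);")
  expect_error(classify_wgt_topology(other, c("S", "L"), "O"),
               "unknown species")
})

test_that("scenario labels ignore leaf order and duplicate swaps", {
  perms <- c("(((S_1:1,L_1:1):1,(S_2:1,L_2:1):1):1,O_1:3);",
             "(((L_1:1,S_1:1):1,(L_2:1,S_2:1):1):1,O_1:3);",
             "(O_1:3,((S_2:1,L_2:1):1,(S_1:1,L_1:1):1):1);",
             "(((S_2:1,L_1:1):1,(S_1:1,L_2:1):1):1,O_1:3);")
  for (nwk in perms) {
    tr <- ape::read.tree(text = nwk)
    expect_equal(classify_wgt_topology(tr, c("S", "L"), "O"), "shared_wgt")
  }
})

test_that("MAPS percentages equal hand counts on five-leaf gene trees", {
  sp <- ape::read.tree(text = "(out:3,(spA:2,spB:2):1);")
  # one shared duplication at the (spA,spB) node; one tree without
  g1 <- ape::read.tree(
    text = "(((spA_g1:1,spB_g1:1):1,(spA_g2:1,spB_g2:1):1):1,out_g1:3);")
  g2 <- ape::read.tree(text = "((spA_g1:2,spB_g1:2):1,out_g1:3);")
  m <- maps_percentages(list(g1, g2), sp)
  row <- m[m$clade == "spA,spB", ]
  expect_equal(row$n_subtrees_examined, 2L)
  expect_equal(row$n_with_shared_duplication, 1L)
  expect_equal(row$percentage, 50)
  # species-specific duplication is not shared by the whole clade
  g3 <- ape::read.tree(
    text = "(((spA_g1:1,spA_g2:1):1,spB_g1:2):1,out_g1:3);")
  m3 <- maps_percentages(list(g3), sp)
  expect_equal(m3[m3$clade == "spA,spB", ]$n_with_shared_duplication, 0L)
})

test_that("forced and absent duplications give 100% and 0%", {
  sp <- ape::read.tree(text = "(out:3,(spA:2,spB:2):1);")
  wgd <- ape::getMRCA(sp, c("spA", "spB"))
  forced <- simulate_gene_family_trees(sp, wgd_node = wgd,
                                       retention_rate = 1,
                                       n_families = 50, seed = 3)
  m <- maps_percentages(forced, sp)
  expect_equal(m[m$clade == "spA,spB", ]$percentage, 100)
  none <- simulate_gene_family_trees(sp, wgd_node = NULL,
                                     n_families = 50, seed = 4)
  m0 <- maps_percentages(none, sp)
  expect_true(all(m0$percentage == 0))
})

test_that("gene-family simulation honours its degenerate limits", {
  sp <- ape::read.tree(text = "(out:3,(spA:2,spB:2):1);")
  trees <- simulate_gene_family_trees(sp, birth = 0, death = 0,
                                      n_families = 20, seed = 5)
  for (tr in trees) {
    expect_equal(sort(tr$tip.label), c("out_g1", "spA_g1", "spB_g1"))
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  }
  expect_error(simulate_gene_family_trees(sp, birth = -1), ">= 0")
  expect_error(simulate_gene_family_trees(sp, wgd_node = 2), "internal")
})

test_that("duplication bursts are recovered at the simulated node", {
  sp <- ape::read.tree(text = "(out:3,(spA:2,spB:2):1);")
  wgd <- ape::getMRCA(sp, c("spA", "spB"))
  trees <- simulate_gene_family_trees(sp, wgd_node = wgd,
                                      retention_rate = 0.2,
                                      n_families = 600, seed = 6)
  m <- maps_percentages(trees, sp)
  pct <- m[m$clade == "spA,spB", ]$percentage
  # binomial 99% band around 20% at n = 600
  expect_lt(abs(pct / 100 - 0.2), 2.58 * sqrt(0.2 * 0.8 / 600) + 1e-9)
  null_m <- maps_percentages(
    simulate_gene_family_trees(sp, n_families = 300, seed = 7), sp)
  cmp <- compare_maps_to_simulations(m, maps_bootstrap(null_m, 100, 1),
                                     maps_bootstrap(m, 100, 2))
  expect_equal(cmp$verdict[cmp$clade == "spA,spB"], "supports_wgd")
  expect_equal(cmp$verdict[cmp$clade == "out,spA,spB"], "no_support")
})

test_that("birth-death gene families remain ultrametric", {
  sp <- ape::read.tree(text = "(out:3,(spA:2,spB:2):1);")
  trees <- simulate_gene_family_trees(sp, birth = 0.15, death = 0.05,
                                      n_families = 40, seed = 9)
  for (tr in trees) expect_true(ape::is.ultrametric(tr, tol = 1e-8))
})
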