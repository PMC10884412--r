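test_that("the paralog graph handles trivial and chained cases", {
  empty <- data.frame(gene_a = character(0), gene_b = character(0))
  g <- build_retention_graph(empty, c("x", "y", "z"))
  cls <- classify_retention_groups(g, "sp")
  expect_equal(nrow(cls$groups), 3L)
  expect_true(all(cls$groups$copy_class == 1L))

  pairs <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"))
  g2 <- build_retention_graph(pairs, c("a", "b", "c", "d"))
  cls2 <- classify_retention_groups(g2, "sp")
  expect_equal(sort(cls2$groups$copy_class), c(1L, 3L))
  three <- cls2$groups[cls2$groups$copy_class == 3L, ]
  expect_equal(three$members, "a;b;c")

  expect_error(build_retention_graph(
    data.frame(gene_a = "a", gene_b = "a"), "a"), "self-loop")
})

test_that("components above the copy cap are flagged, not classified", {
  pairs <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "d"))
  cls <- classify_retention_groups(
    build_retention_graph(pairs, letters[1:4]), "sp")
  expect_equal(nrow(cls$groups), 0L)
  expect_length(cls$flagged, 1L)
  expect_setequal(cls$flagged[[1]], letters[1:4])
})

test_that("groups partition the gene universe regardless of edge order", {
  pairs <- data.frame(gene_a = c("a", "b", "x"), gene_b = c("b", "c", "y"))
  genes <- c("a", "b", "c", "x", "y", "z")
  cls1 <- classify_retention_groups(build_retention_graph(pairs, genes))
  cls2 <- classify_retention_groups(
    build_retention_graph(pairs[c(3, 1, 2), ], genes))
  members1 <- sort(unlist(strsplit(cls1$groups$members, ";")))
  expect_equal(members1, sort(genes))
  expect_equal(cls1$class_counts, cls2$class_counts)
  expect_setequal(cls1$groups$members, cls2$groups$members)
})

test_that("classification matches simulator truth gene by gene", {
  cfg <- quick_config(seed = 23, n_anc_genes = 500)
  sim <- simulate_wgt_genomes(cfg)
  pr <- sim$truth$pairs
  pr <- pr[pr$type == "wgt_paralog" & pr$species_a == "spA", ]
  g <- build_retention_graph(pr[, c("gene_a", "gene_b")],
                             sim$descendants$spA$gene_id)
  cls <- classify_retention_groups(g, "spA")
  lay <- sim$descendants$spA
  truth <- sim$truth$copy_class$spA[match(lay$anc_gene,
                                          sim$truth$copy_class$anc_gene)]
  mem <- strsplit(cls$groups$members, ";", fixed = TRUE)
  inferred <- setNames(rep(cls$groups$copy_class, lengths(mem)),
                       unlist(mem))
  expect_equal(unname(inferred[lay$gene_id]), truth)
})

test_that("outgroup anchoring applies the copy-class pattern", {
  groups_a <- data.frame(group_id = c("A_rg1", "A_rg2"), species = "A",
                         copy_class = c(3L, 1L),
                         members = c("a1;a2;a3", "a9"),
                         stringsAsFactors = FALSE)
  groups_b <- data.frame(group_id = c("B_rg1", "B_rg2"), species = "B",
                         copy_class = c(3L, 1L),
                         members = c("b1;b2;b3", "b9"),
                         stringsAsFactors = FALSE)
  orth <- data.frame(
    outgroup_gene = c(rep("o1", 6), "o2", "o2"),
    species = c(rep("A", 3), rep("B", 3), "A", "B"),
    gene = c("a1", "a2", "a3", "b1", "b2", "b3", "a9", "b9"),
    stringsAsFactors = FALSE)
  res <- anchor_ortholog_groups(groups_a, groups_b, orth)
  expect_equal(res$n_anchored, 1L)
  expect_equal(res$anchored$outgroup_gene, "o1")
  # one ortholog per species fails the (3, 3) pattern
  expect_false("o2" %in% res$anchored$outgroup_gene)
  # orthologs split over two groups in one species are ambiguous
  orth2 <- rbind(orth, data.frame(outgroup_gene = "o1", species = "A",
                                  gene = "a9"))
  res2 <- anchor_ortholog_groups(groups_a, groups_b, orth2)
  expect_equal(res2$ambiguous, "o1")
  expect_equal(res2$n_anchored, 0L)
})

test_that("anchored three-and-three counts match truth on simulations", {
  cfg <- quick_config(seed = 29, n_anc_genes = 400)
  sim <- simulate_wgt_genomes(cfg)
  mk_groups <- function(sp) {
    pr <- sim$truth$pairs
    pr <- pr[pr$type == "wgt_paralog" & pr$species_a == sp, ]
    classify_retention_groups(
      build_retention_graph(pr[, c("gene_a", "gene_b")],
                            sim$descendants[[sp]]$gene_id), sp)$groups
  }
  ga <- mk_groups("spA"); gb <- mk_groups("spB")
  orth <- do.call(rbind, lapply(c("spA", "spB"), function(sp) {
    lay <- sim$descendants[[sp]]
    data.frame(outgroup_gene = lay$anc_gene, species = sp,
               gene = lay$gene_id, stringsAsFactors = FALSE)
  }))
  res <- anchor_ortholog_groups(ga, gb, orth)
  truth_n <- sum(sim$truth$copy_class$spA == 3L &
                   sim$truth$copy_class$spB == 3L)
  expect_equal(res$n_anchored, truth_n)
})

test_that("gene-list intersection equals brute-force set logic", {
  groups <- data.frame(group_id = paste0("g", 1:4), species = "sp",
                       copy_class = c(3L, 2L, 1L, 3L),
                       members = c("a;b;c", "d;e", "f", "g;h;i"),
                       stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_groups_with_gene_list(groups,
                                                    character(0))$groups),
               0L)
  res <- intersect_groups_with_gene_list(groups, c("b", "zz"))
  expect_equal(res$groups$group_id, "g1")
  expect_equal(as.integer(res$counts_by_class[["3"]]), 1L)
  set.seed(7)
  all_genes <- unlist(strsplit(groups$members, ";"))
  for (i in 1:20) {
    pick <- sample(c(all_genes, paste0("x", 1:5)), sample(1:8, 1))
    res <- intersect_groups_with_gene_list(groups, pick)
    brute <- groups$group_id[vapply(strsplit(groups$members, ";"),
                                    function(m) any(m %in% pick),
                                    logical(1))]
    expect_setequal(res$groups$group_id, brute)
  }
})
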