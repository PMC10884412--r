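## Placement of a polyploidy event on the species tree: NJ gene-tree
## building, duplicate-topology scenario classification, and MAPS-style
## subtree-duplication percentages against simulated null/positive bands.

default_species_fun <- function(label) sub("_.*$", "", label)

#' Build a rooted neighbor-joining gene tree
#'
#' Neighbor-joining on a pairwise distance matrix, rooted on the given
#' outgroup. Deterministic for a fixed input (tip order ties resolve by
#' the matrix order).
#'
#' @param d symmetric distance matrix (>= 3 taxa, finite entries) with
#'   labelled rows/columns
#' @param outgroup tip label(s) to root on
#' @return a rooted [ape::phylo] tree
#' @export
build_nj_tree <- function(d, outgroup) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need >= 3 taxa", call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distance", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
}

#' Classify a duplicate-pair gene tree against speciation order
#'
#' For two duplicated leaves from each of two ingroup species (S1, S2, L1,
#' L2), a topology pairing each duplicate clade across species --
#' ((S1,L1),(S2,L2)) -- means the duplication predates the speciation
#' (`shared_wgt`); species-monophyletic duplicates -- ((S1,S2),(L1,L2)) --
#' mean independent, lineage-specific duplications (`lineage_specific`);
#' anything else, including missing leaves or multifurcations, is
#' `unresolved`.
#'
#' @param tree a rooted [ape::phylo] gene tree containing the outgroup
#' @param ingroup_species character vector of the two ingroup species
#' @param outgroup_species outgroup species label
#' @param species_fun maps a leaf label to its species (default: prefix
#'   before the first underscore)
#' @return one of "shared_wgt", "lineage_specific", "unresolved"
#' @export
classify_wgt_topology <- function(tree, ingroup_species, outgroup_species,
                                  species_fun = default_species_fun) {
  sp <- species_fun(tree$tip.label)
  if (any(!sp %in% c(ingroup_species, outgroup_species))) {
    stop("leaf with unknown species: ",
         tree$tip.label[which(!sp %in% c(ingroup_species,
                                         outgroup_species))[1]],
         call. = FALSE)
  }
  s_tips <- tree$tip.label[sp == ingroup_species[1]]
  l_tips <- tree$tip.label[sp == ingroup_species[2]]
  o_tips <- tree$tip.label[sp == outgroup_species]
  if (length(s_tips) != 2L || length(l_tips) != 2L || length(o_tips) < 1L) {
    return("unresolved")
  }
  tr <- tryCatch(ape::root(tree, outgroup = o_tips, resolve.root = TRUE),
                 error = function(e) NULL)
  if (is.null(tr)) return("unresolved")
  ing <- ape::drop.tip(tr, o_tips)
  if (is.null(ing) || ape::Ntip(ing) != 4L || !ape::is.binary(ing)) {
    return("unresolved")
  }
  # children of the ingroup root define the deepest split
  root_node <- ape::Ntip(ing) + 1L
  kids <- ing$edge[ing$edge[, 1] == root_node, 2]
  clades <- lapply(kids, function(k) {
    if (k <= ape::Ntip(ing)) ing$tip.label[k] else
      ape::extract.clade(ing, k)$tip.label
  })
  if (length(clades) != 2L) return("unresolved")
  spc <- lapply(clades, species_fun)
  if (all(lengths(clades) == 2L)) {
    mixed <- vapply(spc, function(s) length(unique(s)) == 2L, logical(1))
    mono <- vapply(spc, function(s) length(unique(s)) == 1L, logical(1))
    if (all(mixed)) return("shared_wgt")
    if (all(mono)) return("lineage_specific")
  }
  "unresolved"
}

#' Tally topology scenarios over a collection of gene trees
#'
#' @param trees list of rooted gene trees
#' @inheritParams classify_wgt_topology
#' @return table over shared_wgt / lineage_specific / unresolved
#' @export
count_wgt_scenarios <- function(trees, ingroup_species, outgroup_species,
                                species_fun = default_species_fun) {
  labs <- vapply(trees, classify_wgt_topology, character(1),
                 ingroup_species = ingroup_species,
                 outgroup_species = outgroup_species,
                 species_fun = species_fun)
  table(factor(labs, levels = c("shared_wgt", "lineage_specific",
                                "unresolved")))
}

phylo_clades <- function(tree) {
  n <- ape::Ntip(tree)
  lapply((n + 1L):(n + tree$Nnode), function(nd) {
    ape::extract.clade(tree, nd)$tip.label
  })
}

# duplication nodes by species overlap; returns per-node species sets of
# the two child subtrees
gene_tree_duplications <- function(tree, species_fun) {
  n <- ape::Ntip(tree)
  out <- list()
  for (nd in (n + 1L):(n + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    if (length(kids) != 2L) next
    sets <- lapply(kids, function(k) {
      tips <- if (k <= n) tree$tip.label[k] else
        ape::extract.clade(tree, k)$tip.label
      unique(species_fun(tips))
    })
    if (length(intersect(sets[[1]], sets[[2]])) >= 1L) {
      out[[length(out) + 1L]] <- sets
    }
  }
  out
}

#' MAPS-style subtree duplication percentages
#'
#' For each internal node of the species tree, the percentage of gene
#' trees containing a duplication shared by every species descended from
#' that node. A gene-tree node is a duplication if its two child subtrees
#' overlap in species; it is assigned to the species-tree node whose clade
#' equals the species union beneath it, and supports that node only if
#' both children contain every species of the clade.
#'
#' @param gene_trees list of rooted [ape::phylo] gene trees
#' @param species_tree rooted [ape::phylo] species tree; leaf labels are
#'   species names
#' @param species_fun maps gene-tree leaf labels to species
#' @return data.frame of class `maps_result`: one row per species-tree
#'   internal node with >= 2 species (`node`, `clade`,
#'   `n_subtrees_examined`, `n_with_shared_duplication`, `percentage`)
#' @export
maps_percentages <- function(gene_trees, species_tree,
                             species_fun = default_species_fun) {
  all_sp <- species_tree$tip.label
  for (gt in gene_trees) {
    sp <- unique(species_fun(gt$tip.label))
    if (any(!sp %in% all_sp)) {
      stop("gene tree species not in species tree: ",
           setdiff(sp, all_sp)[1], call. = FALSE)
    }
  }
  n <- ape::Ntip(species_tree)
  nodes <- (n + 1L):(n + species_tree$Nnode)
  clades <- lapply(nodes, function(nd) {
    sort(ape::extract.clade(species_tree, nd)$tip.label)
  })
  keep <- lengths(clades) >= 2L
  nodes <- nodes[keep]; clades <- clades[keep]
  dup_sets <- lapply(gene_trees, gene_tree_duplications, species_fun)
  tree_species <- lapply(gene_trees, function(gt) {
    unique(species_fun(gt$tip.label))
  })
  examined <- vapply(clades, function(clade) {
    vapply(tree_species, function(s) all(clade %in% s), logical(1))
  }, logical(length(gene_trees)))
  examined <- matrix(examined, nrow = length(gene_trees))
  support <- vapply(seq_along(clades), function(i) {
    clade <- clades[[i]]
    vapply(seq_along(gene_trees), function(g) {
      if (!examined[g, i]) return(FALSE)
      for (d in dup_sets[[g]]) {
        un <- sort(unique(c(d[[1]], d[[2]])))
        if (identical(un, clade) &&
            all(clade %in% d[[1]]) && all(clade %in% d[[2]])) return(TRUE)
      }
      FALSE
    }, logical(1))
  }, logical(length(gene_trees)))
  examined <- matrix(examined, nrow = length(gene_trees))
  support <- matrix(support, nrow = length(gene_trees))
  ne <- colSums(examined); ns <- colSums(support)
  out <- data.frame(node = nodes,
                    clade = vapply(clades, paste, character(1),
                                   collapse = ","),
                    n_subtrees_examined = ne,
                    n_with_shared_duplication = ns,
                    percentage = ifelse(ne > 0, 100 * ns / ne, NA_real_),
                    stringsAsFactors = FALSE)
  keep_nodes <- ne > 0   # unexamined nodes are absent, not 0%
  out <- out[keep_nodes, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "examined") <- examined[, keep_nodes, drop = FALSE]
  attr(out, "support") <- support[, keep_nodes, drop = FALSE]
  class(out) <- c("maps_result", class(out))
  out
}

#' Bootstrap replicates of a MAPS result
#'
#' Resamples gene trees with replacement (using the per-tree support
#' indicators carried by [maps_percentages()]) and recomputes the per-node
#' percentages, giving the bootstrap bands used to compare observed data
#' against null and positive simulations.
#'
#' @param maps a `maps_result` from [maps_percentages()]
#' @param n_reps bootstrap replicates (default 200)
#' @param seed RNG seed
#' @return list of `n_reps` data.frames shaped like `maps`
#' @export
maps_bootstrap <- function(maps, n_reps = 200L, seed = 1L) {
  examined <- attr(maps, "examined")
  support <- attr(maps, "support")
  if (is.null(support)) {
    stop("maps_result lacks per-tree support indicators", call. = FALSE)
  }
  n_trees <- nrow(support)
  with_seed(child_seed(seed, 910L), {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(n_trees, n_trees, replace = TRUE)
      ne <- colSums(examined[idx, , drop = FALSE])
      ns <- colSums(support[idx, , drop = FALSE])
      data.frame(node = maps$node, clade = maps$clade,
                 n_subtrees_examined = ne,
                 n_with_shared_duplication = ns,
                 percentage = ifelse(ne > 0, 100 * ns / ne, NA_real_),
                 stringsAsFactors = FALSE)
    })
  })
}

#' Compare observed MAPS percentages against simulated bands
#'
#' Per species-tree node, the observed percentage is compared with the
#' 2.5-97.5 percentile bands of the null and positive simulations: above
#' the null band and at or above the lower positive band is
#' `supports_wgd`; at or below the null median is `no_support`; otherwise
#' `ambiguous`.
#'
#' @param observed a `maps_result`
#' @param null_sims,positive_sims lists of `maps_result` objects from
#'   repeated simulations (e.g. bootstrap replicates)
#' @return data.frame: per node the observed percentage, both bands and
#'   the verdict
#' @export
compare_maps_to_simulations <- function(observed, null_sims,
                                        positive_sims) {
  stopifnot(length(null_sims) >= 1L, length(positive_sims) >= 1L)
  band <- function(sims, clade) {
    v <- vapply(sims, function(s) {
      i <- match(clade, s$clade)
      if (is.na(i)) stop("mismatched node sets between observed and ",
                         "simulated MAPS results", call. = FALSE)
      s$percentage[i]
    }, numeric(1))
    c(lo = unname(quantile(v, 0.025)), med = unname(median(v)),
      hi = unname(quantile(v, 0.975)))
  }
  rows <- lapply(seq_len(nrow(observed)), function(i) {
    clade <- observed$clade[i]
    nb <- band(null_sims, clade)
    pb <- band(positive_sims, clade)
    obs <- observed$percentage[i]
    verdict <- if (obs <= nb["med"]) "no_support" else
      if (obs > nb["hi"] && obs >= pb["lo"]) "supports_wgd" else "ambiguous"
    data.frame(node = observed$node[i], clade = clade, observed = obs,
               null_lo = nb["lo"], null_median = nb["med"],
               null_hi = nb["hi"], positive_lo = pb["lo"],
               positive_hi = pb["hi"], verdict = verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
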