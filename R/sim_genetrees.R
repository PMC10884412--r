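## Gene-family tree simulator: birth-death along a dated species tree,
## with an optional whole-genome duplication at one species-tree node
## whose extra copy is retained with a fixed probability.

resolve_wgd_node <- function(species_tree, wgd_node) {
  if (is.null(wgd_node)) return(NULL)
  node <- if (is.character(wgd_node)) {
    if (length(wgd_node) < 2L) {
      stop("wgd_node as species labels needs >= 2 species", call. = FALSE)
    }
    ape::getMRCA(species_tree, wgd_node)
  } else as.integer(wgd_node)
  n <- ape::Ntip(species_tree)
  if (is.na(node) || node <= n || node > n + species_tree$Nnode) {
    stop("wgd_node must be an internal node of the species tree",
         call. = FALSE)
  }
  node
}

#' Simulate gene-family trees under birth-death with an optional WGD
#'
#' Each family starts as a single gene lineage at the species-tree root.
#' Lineages duplicate (birth) and die (death) with exponential waiting
#' times along species-tree branches and split at speciations. When a
#' lineage crosses `wgd_node`, it duplicates there and the extra copy is
#' retained with probability `retention_rate`. Gene trees are ultrametric
#' on the species-tree timescale; leaves are labelled
#' `<species>_g<index>`.
#'
#' @param species_tree rooted ultrametric [ape::phylo] with branch lengths
#' @param birth,death gene birth and death rates per lineage per unit time
#'   (>= 0)
#' @param wgd_node `NULL` (no WGD / null simulation), an internal node
#'   number, or a character vector of species whose MRCA carries the WGD
#' @param retention_rate survival probability of the WGD's extra copy
#' @param n_families number of families to return
#' @param seed RNG seed
#' @param complete_only keep only families with every species represented
#'   (the usual gene-family filter; guaranteed when death = 0)
#' @return list of rooted [ape::phylo] gene trees
#' @export
simulate_gene_family_trees <- function(species_tree, birth = 0, death = 0,
                                       wgd_node = NULL,
                                       retention_rate = 0.2,
                                       n_families = 2000L, seed = 1L,
                                       complete_only = TRUE) {
  if (birth < 0 || death < 0) stop("rates must be >= 0", call. = FALSE)
  stopifnot_prob(retention_rate, "retention_rate")
  wgd <- resolve_wgd_node(species_tree, wgd_node)
  ntip <- ape::Ntip(species_tree)
  edge_len <- function(child) {
    species_tree$edge.length[species_tree$edge[, 2] == child]
  }
  children_of <- function(node) species_tree$edge[species_tree$edge[, 1] == node, 2]
  with_seed(child_seed(seed, 808L), {
    counter <- new.env(parent = emptyenv())
    new_leaf <- function(sp) {
      k <- (get0(sp, envir = counter, ifnotfound = 0L)) + 1L
      assign(sp, k, envir = counter)
      sprintf("%s_g%d", sp, k)
    }
    speciate <- function(node) {
      if (node <= ntip) {
        return(list(str = new_leaf(species_tree$tip.label[node]), len = 0))
      }
      subs <- list()
      for (ch in children_of(node)) {
        s <- along_branch(ch, edge_len(ch))
        if (!is.null(s)) subs[[length(subs) + 1L]] <- s
      }
      if (length(subs) == 0L) return(NULL)
      if (length(subs) == 1L) return(subs[[1]])
      list(str = paste0("(", subs[[1]]$str, ":", subs[[1]]$len, ",",
                        subs[[2]]$str, ":", subs[[2]]$len, ")"), len = 0)
    }
    arrive <- function(node) {
      if (!is.null(wgd) && node == wgd && runif(1) < retention_rate) {
        a <- speciate(node); b <- speciate(node)
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a)) return(b)
        if (is.null(b)) return(a)
        return(list(str = paste0("(", a$str, ":", a$len, ",", b$str, ":",
                                 b$len, ")"), len = 0))
      }
      speciate(node)
    }
    along_branch <- function(child, T) {
      rate <- birth + death
      ev_t <- if (rate > 0) rexp(1L, rate) else Inf
      if (ev_t >= T) {
        s <- arrive(child)
        if (is.null(s)) return(NULL)
        s$len <- s$len + T
        return(s)
      }
      if (runif(1) >= birth / rate) return(NULL)  # death
      a <- along_branch(child, T - ev_t)
      b <- along_branch(child, T - ev_t)
      if (is.null(a) && is.null(b)) return(NULL)
      if (is.null(a)) { b$len <- b$len + ev_t; return(b) }
      if (is.null(b)) { a$len <- a$len + ev_t; return(a) }
      list(str = paste0("(", a$str, ":", a$len, ",", b$str, ":", b$len,
                        ")"), len = ev_t)
    }
    trees <- vector("list", n_families)
    got <- 0L
    attempts <- 0L
    max_attempts <- 100L * n_families
    root <- ntip + 1L
    while (got < n_families && attempts < max_attempts) {
      attempts <- attempts + 1L
      for (sp in species_tree$tip.label) assign(sp, 0L, envir = counter)
      res <- arrive(root)
      if (is.null(res)) next
      tr <- ape::read.tree(text = paste0(res$str, ";"))
      if (is.null(tr) || ape::Ntip(tr) < 2L) next
      if (complete_only) {
        sp <- unique(default_species_fun(tr$tip.label))
        if (!all(species_tree$tip.label %in% sp)) next
      }
      got <- got + 1L
      trees[[got]] <- tr
    }
    if (got < n_families) {
      stop(sprintf(paste0("only %d of %d families survived the ",
                          "completeness filter; lower the death rate"),
                   got, n_families), call. = FALSE)
    }
    pk_log("simulate_gene_family_trees", n_families = n_families,
           birth = birth, death = death,
           wgd = if (is.null(wgd)) "none" else wgd,
           retention_rate = retention_rate)
    trees
  })
}
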