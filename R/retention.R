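## Paralog retention groups: graph of Ks-filtered syntenic pairs,
## connected-component classification into one/two/three-copy groups,
## outgroup anchoring, gene-list intersection.

#' Build the paralog graph from retained duplicate pairs
#'
#' Nodes are all annotated genes of the species; edges are the Ks-filtered
#' syntenic paralog pairs. Edge multiplicity is collapsed; a self-loop is
#' an error.
#'
#' @param retained_pairs data.frame with columns `gene_a`, `gene_b`
#' @param all_genes character vector of every gene id in the species
#'   (isolated genes become one-copy groups)
#' @return an [igraph][igraph::igraph-package] undirected simple graph
#' @export
build_retention_graph <- function(retained_pairs, all_genes) {
  if (nrow(retained_pairs) > 0 &&
      any(retained_pairs$gene_a == retained_pairs$gene_b)) {
    stop("self-loop pair in retained_pairs", call. = FALSE)
  }
  vertices <- union(all_genes,
                    c(retained_pairs$gene_a, retained_pairs$gene_b))
  g <- igraph::graph_from_data_frame(
    retained_pairs[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = vertices))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Classify retention groups from the paralog graph
#'
#' Connected components of size 1, 2 and 3 are one-, two- and three-copy
#' retention groups. Components larger than the multiplication level
#' (default 3) cannot be assigned a copy class without inventing a
#' splitting rule, so they are flagged and excluded from class counts.
#'
#' @param graph from [build_retention_graph()]
#' @param species species label stored on the groups
#' @param max_class largest recognised copy class (default 3)
#' @return list with `groups` (data.frame: `group_id`, `species`,
#'   `copy_class`, `members` semicolon-joined), `class_counts` (table over
#'   1..max_class), and `flagged` (members of oversized components)
#' @export
classify_retention_groups <- function(graph, species = "sp",
                                      max_class = 3L) {
  comp <- igraph::components(graph)
  members <- split(names(comp$membership), comp$membership)
  sizes <- lengths(members)
  ord <- order(vapply(members, `[`, character(1), 1L))
  members <- members[ord]; sizes <- sizes[ord]
  ok <- sizes <= max_class
  groups <- data.frame(
    group_id = sprintf("%s_rg%05d", species, seq_len(sum(ok))),
    species = rep(species, sum(ok)),
    copy_class = as.integer(sizes[ok]),
    members = vapply(members[ok], function(m) {
      paste(sort(m), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  counts <- table(factor(groups$copy_class, levels = seq_len(max_class)))
  flagged <- members[!ok]
  pk_log("classify_retention_groups", species = species,
         n_groups = nrow(groups), n_flagged = length(flagged),
         class_counts = paste(counts, collapse = "/"))
  list(groups = groups, class_counts = counts, flagged = flagged)
}

group_lookup <- function(groups) {
  mem <- strsplit(groups$members, ";", fixed = TRUE)
  data.frame(gene = unlist(mem),
             group_id = rep(groups$group_id, lengths(mem)),
             copy_class = rep(groups$copy_class, lengths(mem)),
             stringsAsFactors = FALSE)
}

#' Anchor retention groups of two species to outgroup orthologs
#'
#' Joins each outgroup gene to the retention group of its orthologs in
#' each ingroup species and filters to a requested copy-class pattern --
#' e.g. pattern `c(3, 3)` selects outgroup genes whose orthologs form a
#' three-copy group in both species. An outgroup gene whose orthologs fall
#' into two different groups of one species is flagged ambiguous and never
#' counted.
#'
#' @param groups_a,groups_b `groups` data.frames from
#'   [classify_retention_groups()]
#' @param orthologs data.frame with columns `outgroup_gene`, `species`,
#'   `gene` (ingroup gene id)
#' @param pattern length-2 integer copy-class pattern (default `c(3, 3)`)
#' @return list with `anchored` (data.frame: `outgroup_gene`, `group_a`,
#'   `group_b`, `class_a`, `class_b`), `n_anchored`, and `ambiguous`
#'   (outgroup gene ids)
#' @export
anchor_ortholog_groups <- function(groups_a, groups_b, orthologs,
                                   pattern = c(3L, 3L)) {
  lk <- list(a = group_lookup(groups_a), b = group_lookup(groups_b))
  sp <- list(a = groups_a$species[1], b = groups_b$species[1])
  rows <- list(); ambiguous <- character(0)
  for (og in unique(orthologs$outgroup_gene)) {
    rec <- list()
    amb <- FALSE
    for (side in c("a", "b")) {
      genes <- orthologs$gene[orthologs$outgroup_gene == og &
                                orthologs$species == sp[[side]]]
      hit <- lk[[side]][lk[[side]]$gene %in% genes, , drop = FALSE]
      gids <- unique(hit$group_id)
      if (length(gids) > 1L) { amb <- TRUE; break }
      rec[[side]] <- if (length(gids) == 1L) hit[1, ] else NULL
    }
    if (amb) { ambiguous <- c(ambiguous, og); next }
    if (is.null(rec$a) || is.null(rec$b)) next
    rows[[length(rows) + 1L]] <- data.frame(
      outgroup_gene = og, group_a = rec$a$group_id, group_b = rec$b$group_id,
      class_a = rec$a$copy_class, class_b = rec$b$copy_class,
      stringsAsFactors = FALSE)
  }
  anchored <- if (length(rows)) do.call(rbind, rows) else
    data.frame(outgroup_gene = character(0), group_a = character(0),
               group_b = character(0), class_a = integer(0),
               class_b = integer(0))
  keep <- anchored$class_a == pattern[1] & anchored$class_b == pattern[2]
  anchored <- anchored[keep, , drop = FALSE]
  rownames(anchored) <- NULL
  list(anchored = anchored, n_anchored = nrow(anchored),
       ambiguous = ambiguous)
}

#' Intersect retention groups with a gene list
#'
#' Counts groups having at least one member in `gene_list`, by copy class
#' (the style of summary used for, e.g., groups with an up-regulated copy).
#'
#' @param groups `groups` data.frame from [classify_retention_groups()]
#' @param gene_list character vector of gene ids
#' @return list with `groups` (the matching subset) and `counts_by_class`
#' @export
intersect_groups_with_gene_list <- function(groups, gene_list) {
  mem <- strsplit(groups$members, ";", fixed = TRUE)
  hit <- vapply(mem, function(m) any(m %in% gene_list), logical(1))
  sel <- groups[hit, , drop = FALSE]
  rownames(sel) <- NULL
  counts <- table(factor(sel$copy_class,
                         levels = sort(unique(groups$copy_class))))
  list(groups = sel, counts_by_class = counts)
}
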