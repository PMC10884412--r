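## Genome-evolution simulator: triplicate an ancestor, split into two
## lineages, fractionate and rearrange each independently, with full ground
## truth (copy classes, true pair Ks, replayable rearrangement log).

GENE_SPAN <- 1000L
GENE_SPACING <- 2000L

make_layout <- function(gene_id, species, chromosome, anc_gene, anc_chrom,
                        subgenome, sign) {
  df <- data.frame(gene_id = gene_id, species = species,
                   chromosome = chromosome, anc_gene = anc_gene,
                   anc_chrom = anc_chrom, subgenome = subgenome,
                   sign = sign, stringsAsFactors = FALSE)
  recompute_coords(df)
}

# Ranks/coordinates follow chromosome order; called after every structural
# change so the layout is always internally consistent.
recompute_coords <- function(df) {
  df <- df[order(match(df$chromosome, unique(df$chromosome))), , drop = FALSE]
  rank <- unlist(lapply(split(seq_len(nrow(df)), df$chromosome)[unique(df$chromosome)],
                        seq_along), use.names = FALSE)
  df$rank <- rank
  df$start <- (rank - 1L) * GENE_SPACING + 1L
  df$end <- df$start + GENE_SPAN - 1L
  df$strand <- ifelse(df$sign >= 0, "+", "-")
  rownames(df) <- NULL
  df
}

ancestral_layout <- function(config) {
  n <- config$n_anc_genes
  nchr <- config$n_anc_chromosomes
  chrom_of <- rep(seq_len(nchr), length.out = 0)
  sizes <- rep(n %/% nchr, nchr)
  extra <- n %% nchr
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  chrom <- rep(paste0("chr", seq_len(nchr)), sizes)
  gid <- sprintf("anc_g%05d", seq_len(n))
  make_layout(gid, "anc", chrom, gid, chrom, "anc", rep(1L, n))
}

subgenome_loss_probs <- function(config) {
  m <- config$wgt_multiplier
  if (m == 1L || config$bias == 0) return(rep(config$loss_prob, m))
  w <- 1 + config$bias * (2 * (seq_len(m) - 1) / (m - 1) - 1)
  pmin(pmax(config$loss_prob * w, 0), 1)
}

apply_event <- function(layout, ev) {
  if (ev$type == "inversion") {
    idx <- which(layout$chromosome == ev$chrom)
    if (length(idx) < 2L) return(layout)
    seg <- idx[ev$i:ev$j]
    block <- layout[rev(seg), , drop = FALSE]
    block$sign <- -block$sign
    layout[seg, ] <- block
  } else if (ev$type == "fusion") {
    sel <- layout$chromosome %in% c(ev$chrom, ev$chrom_b)
    ord <- c(which(layout$chromosome == ev$chrom),
             which(layout$chromosome == ev$chrom_b))
    layout <- rbind(layout[-ord, , drop = FALSE],
                    transform(layout[ord, , drop = FALSE],
                              chromosome = ev$new_name))
  } else if (ev$type == "fission") {
    idx <- which(layout$chromosome == ev$chrom)
    if (length(idx) < 2L) return(layout)
    left <- idx[seq_len(ev$i)]
    right <- setdiff(idx, left)
    layout$chromosome[left] <- paste0(ev$new_name, ".1")
    layout$chromosome[right] <- paste0(ev$new_name, ".2")
  } else stop("unknown event type: ", ev$type)
  recompute_coords(layout)
}

simulate_events <- function(layout, config, lineage) {
  n_inv <- rpois(1L, config$inv_rate)
  n_fus <- rpois(1L, config$fus_rate)
  n_fis <- rpois(1L, config$fis_rate)
  types <- sample(rep(c("inversion", "fusion", "fission"),
                      c(n_inv, n_fus, n_fis)))
  log <- list()
  counter <- 0L
  for (type in types) {
    chroms <- unique(layout$chromosome)
    sizes <- table(layout$chromosome)[chroms]
    counter <- counter + 1L
    if (type == "inversion") {
      ok <- chroms[sizes >= 2L]
      if (!length(ok)) next
      ch <- sample(ok, 1L)
      k <- sizes[[ch]]
      ij <- sort(sample.int(k, 2L))
      ev <- list(type = "inversion", chrom = ch, i = ij[1], j = ij[2])
    } else if (type == "fusion") {
      if (length(chroms) < 2L) next
      ab <- sample(chroms, 2L)
      ev <- list(type = "fusion", chrom = ab[1], chrom_b = ab[2],
                 new_name = sprintf("%s_fus%d", lineage, counter))
    } else {
      ok <- chroms[sizes >= 2L]
      if (!length(ok)) next
      ch <- sample(ok, 1L)
      ev <- list(type = "fission", chrom = ch,
                 i = sample.int(sizes[[ch]] - 1L, 1L),
                 new_name = sprintf("%s_fis%d", lineage, counter))
    }
    ev$lineage <- lineage
    layout <- apply_event(layout, ev)
    log[[length(log) + 1L]] <- ev
  }
  list(layout = layout, log = log)
}

post_wgt_layout <- function(ancestor, config, species, survival) {
  m <- config$wgt_multiplier
  parts <- lapply(seq_len(m), function(k) {
    keep <- survival[, k]
    df <- ancestor[keep, , drop = FALSE]
    df$subgenome <- LETTERS[k]
    df$chromosome <- paste0(df$anc_chrom, "_", LETTERS[k])
    df$species <- species
    df
  })
  df <- do.call(rbind, parts)
  df$gene_id <- sprintf("%s_g%05d", species, seq_len(nrow(df)))
  recompute_coords(df)
}

#' Simulate a triplicated ancestor and two fractionating descendants
#'
#' Reproduces the history the pipeline is designed to detect: an ancestral
#' genome undergoes a whole-genome multiplication (default triplication),
#' the polyploid then splits into two lineages, and each lineage
#' independently loses duplicated copies (fractionation, with at most
#' multiplier-1 losses per ancestral gene so every gene keeps one copy) and
#' rearranges its chromosomes by inversion, fusion and fission.
#'
#' @param config a [sim_config()]
#' @return a list of class `wgt_sim` with elements `ancestor` (gene table of
#'   the unduplicated ancestor, usable as an outgroup proxy), `descendants`
#'   (named list of two gene tables, species `spA` and `spB`), and `truth`
#'   (`sim_truth`: per-gene copy classes, true pair Ks, survival matrices
#'   and a replayable rearrangement log)
#' @export
simulate_wgt_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$wgt_multiplier < 1L) stop("wgt_multiplier must be >= 1")
  with_seed(child_seed(config$seed, 101L), {
    anc <- ancestral_layout(config)
    m <- config$wgt_multiplier
    p <- subgenome_loss_probs(config)
    species <- c("spA", "spB")
    descendants <- list()
    survival <- list()
    logs <- list()
    classes <- list()
    for (sp in species) {
      surv <- matrix(TRUE, nrow(anc), m)
      if (m > 1L && any(p > 0)) {
        for (k in seq_len(m)) surv[, k] <- runif(nrow(anc)) >= p[k]
        lost_all <- which(rowSums(surv) == 0L)
        while (length(lost_all)) {  # condition on >= 1 surviving copy
          for (k in seq_len(m)) {
            surv[lost_all, k] <- runif(length(lost_all)) >= p[k]
          }
          lost_all <- lost_all[rowSums(surv[lost_all, , drop = FALSE]) == 0L]
        }
      }
      lay <- post_wgt_layout(anc, config, sp, surv)
      re <- simulate_events(lay, config, sp)
      descendants[[sp]] <- re$layout
      survival[[sp]] <- surv
      logs[[sp]] <- re$log
      classes[[sp]] <- rowSums(surv)
    }
    copy_class <- data.frame(anc_gene = anc$gene_id,
                             spA = classes$spA, spB = classes$spB,
                             stringsAsFactors = FALSE)
    pairs <- sim_true_pairs(anc, descendants, config)
    truth <- list(copy_class = copy_class, survival = survival,
                  event_log = logs, pairs = pairs, config = config)
    class(truth) <- "sim_truth"
    out <- list(ancestor = anc, descendants = descendants, truth = truth)
    class(out) <- "wgt_sim"
    pk_log("simulate_wgt_genomes", n_anc_genes = config$n_anc_genes,
           multiplier = m, loss_prob = config$loss_prob,
           spA_genes = nrow(descendants$spA),
           spB_genes = nrow(descendants$spB))
    out
  })
}

# True pair table: within-species WGT paralog pairs and cross-species
# ortholog pairs (one representative copy per lineage), each with a
# lognormal true Ks around its peak.
sim_true_pairs <- function(anc, descendants, config) {
  rows <- list()
  for (sp in names(descendants)) {
    lay <- descendants[[sp]]
    split_genes <- split(lay$gene_id, lay$anc_gene)
    multi <- split_genes[lengths(split_genes) >= 2L]
    if (length(multi)) {
      prs <- lapply(multi, function(g) t(combn(sort(g), 2L)))
      mat <- do.call(rbind, prs)
      rows[[sp]] <- data.frame(gene_a = mat[, 1], gene_b = mat[, 2],
                               type = "wgt_paralog", species_a = sp,
                               species_b = sp,
                               anc_gene = rep(names(multi),
                                              vapply(prs, nrow, 1L)),
                               stringsAsFactors = FALSE)
    }
  }
  la <- descendants[[1]]; lb <- descendants[[2]]
  ga <- vapply(split(la$gene_id, la$anc_gene), `[`, character(1), 1L)
  gb <- vapply(split(lb$gene_id, lb$anc_gene), `[`, character(1), 1L)
  shared <- intersect(names(ga), names(gb))
  rows$orth <- data.frame(gene_a = unname(ga[shared]),
                          gene_b = unname(gb[shared]),
                          type = "ortholog",
                          species_a = names(descendants)[1],
                          species_b = names(descendants)[2],
                          anc_gene = shared, stringsAsFactors = FALSE)
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  peak <- ifelse(pairs$type == "wgt_paralog", config$ks_wgt_peak,
                 config$ks_speciation_peak)
  pairs$true_ks <- rlnorm(nrow(pairs), meanlog = log(peak),
                          sdlog = config$ks_sd)
  pairs$true_ka <- pairs$true_ks * config$ka_omega
  pairs
}

#' Replay a recorded rearrangement log
#'
#' Reconstructs a descendant layout from the ancestor, the recorded
#' survival matrix and the event log; used to verify that the truth record
#' fully determines the simulated genomes.
#'
#' @param sim a `wgt_sim`
#' @param species which descendant to rebuild
#' @return the reconstructed gene table
#' @export
replay_rearrangements <- function(sim, species) {
  stopifnot(inherits(sim, "wgt_sim"))
  lay <- post_wgt_layout(sim$ancestor, sim$truth$config, species,
                         sim$truth$survival[[species]])
  for (ev in sim$truth$event_log[[species]]) lay <- apply_event(lay, ev)
  lay
}

#' Homology hits between two simulated gene tables
#'
#' Emits one high-confidence hit per gene pair sharing an ancestral gene
#' (the simulator's notion of homology), in BLAST tabular style, plus an
#' optional fraction of random noise hits that the published filters should
#' remove.
#'
#' @param layout_a,layout_b gene tables from [simulate_wgt_genomes()]
#' @param seed RNG seed
#' @param noise_frac noise hits as a fraction of true hits; noise rows get
#'   identity < 30, e-value >= 1e-10 or coverage < 0.3 so the standard
#'   filter excludes them
#' @return data.frame of homology hits (see [read_homology()])
#' @export
sim_homology_hits <- function(layout_a, layout_b, seed = 1L,
                              noise_frac = 0.1) {
  with_seed(child_seed(seed, 202L), {
    key <- merge(layout_a[, c("gene_id", "anc_gene")],
                 layout_b[, c("gene_id", "anc_gene")],
                 by = "anc_gene", suffixes = c("_a", "_b"))
    same <- identical(layout_a$species[1], layout_b$species[1])
    if (same) key <- key[key$gene_id_a != key$gene_id_b, , drop = FALSE]
    n <- nrow(key)
    hits <- data.frame(query = key$gene_id_a, subject = key$gene_id_b,
                       identity = runif(n, 70, 99),
                       evalue = 10^runif(n, -180, -50),
                       coverage_q = runif(n, 0.8, 1),
                       coverage_s = runif(n, 0.8, 1),
                       bitscore = runif(n, 200, 900),
                       stringsAsFactors = FALSE)
    n_noise <- round(noise_frac * n)
    if (n_noise > 0) {
      noise <- data.frame(query = sample(layout_a$gene_id, n_noise, TRUE),
                          subject = sample(layout_b$gene_id, n_noise, TRUE),
                          identity = runif(n_noise, 15, 28),
                          evalue = 10^runif(n_noise, -9, -2),
                          coverage_q = runif(n_noise, 0.05, 0.25),
                          coverage_s = runif(n_noise, 0.05, 0.25),
                          bitscore = runif(n_noise, 30, 60),
                          stringsAsFactors = FALSE)
      noise <- noise[noise$query != noise$subject, , drop = FALSE]
      hits <- rbind(hits, noise)
    }
    rownames(hits) <- NULL
    hits
  })
}
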