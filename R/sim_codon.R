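## Codon-pair generator for Ka/Ks estimator validation.
##
## Ancestral codons are drawn from six fourfold-degenerate families
## (GGN, GCN, GTN, CCN, TCN, ACN). Within this codon universe every
## third-position change is synonymous and a genuine four-state neutral
## site, and every first/second-position single-nucleotide move between
## families is nonsynonymous and stop-free, so the Nei-Gojobori site counts
## are exactly S = 1 and N = 2 per codon and the Jukes-Cantor correction is
## the correct inverse of the mutation process.

FOURFOLD_PREFIX <- c("GG", "GC", "GT", "CC", "TC", "AC")

# single-nucleotide neighbours within the fourfold family set
FF_NEIGHBORS <- list(GG = c("GC", "GT"),
                     GC = c("GG", "GT", "AC", "CC", "TC"),
                     GT = c("GG", "GC"),
                     CC = c("GC", "AC", "TC"),
                     TC = c("GC", "AC", "CC"),
                     AC = c("GC", "CC", "TC"))

# expected synonymous p-distance under the JC event process
expected_ps <- function(ks) 0.75 * (1 - exp(-4 * ks / 3))

random_cds <- function(n_codons) {
  paste0(sample(FOURFOLD_PREFIX, n_codons, replace = TRUE),
         sample(BASES, n_codons, replace = TRUE), collapse = "")
}

mutate_cds <- function(cds, ks, ka) {
  n_codons <- nchar(cds) / 3L
  codons <- split_codons(cds)
  pre <- substr(codons, 1L, 2L)
  third <- substr(codons, 3L, 3L)
  n_syn <- rpois(1L, ks * n_codons)        # S sites = n_codons
  n_non <- rpois(1L, ka * 2 * n_codons)    # N sites = 2 * n_codons
  if (n_syn > 0) {
    for (i in sample.int(n_codons, n_syn, replace = TRUE)) {
      third[i] <- sample(setdiff(BASES, third[i]), 1L)
    }
  }
  if (n_non > 0) {
    for (i in sample.int(n_codons, n_non, replace = TRUE)) {
      pre[i] <- sample(FF_NEIGHBORS[[pre[i]]], 1L)
    }
  }
  paste0(pre, third, collapse = "")
}

#' Simulate aligned in-frame CDS pairs with known divergence
#'
#' For each requested pair, builds an ancestral coding sequence and applies
#' Poisson numbers of synonymous and nonsynonymous substitution events at
#' rates set by the pair's target Ks and Ka. Synonymous events follow a
#' four-state Jukes-Cantor process at fourfold-degenerate third positions,
#' so the NG86 estimator is consistent for the target Ks.
#'
#' @param truth a `sim_truth` (from [simulate_wgt_genomes()]) whose `pairs`
#'   table supplies pair identities and target `true_ks`/`true_ka`; or a
#'   data.frame with columns `gene_a`, `gene_b`, `true_ks` and optionally
#'   `true_ka` (default 0)
#' @param config a [sim_config()]; supplies `gene_length_codons` and the seed
#' @return the pair table with `cds_a` and `cds_b` columns appended
#' @export
simulate_codon_pairs <- function(truth, config) {
  pairs <- if (inherits(truth, "sim_truth")) truth$pairs else truth
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b", "true_ks") %in%
                                        names(pairs)))
  if (is.null(pairs$true_ka)) pairs$true_ka <- 0
  if (any(pairs$true_ks < 0) || any(pairs$true_ka < 0)) {
    stop("target Ks/Ka must be non-negative", call. = FALSE)
  }
  sat <- expected_ps(pairs$true_ks) >= 0.70
  if (any(sat)) {
    stop(sprintf(paste0("%d pair(s) have target Ks beyond the Jukes-Cantor",
                        " saturation guard (expected p-distance >= 0.70);",
                        " largest offending Ks = %.3f"),
                 sum(sat), max(pairs$true_ks[sat])), call. = FALSE)
  }
  with_seed(child_seed(config$seed, 303L), {
    n_codons <- config$gene_length_codons
    cds_a <- character(nrow(pairs))
    cds_b <- character(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      anc <- random_cds(n_codons)
      cds_a[i] <- anc
      cds_b[i] <- mutate_cds(anc, pairs$true_ks[i], pairs$true_ka[i])
    }
    pairs$cds_a <- cds_a
    pairs$cds_b <- cds_b
    pk_log("simulate_codon_pairs", n_pairs = nrow(pairs),
           n_codons = n_codons)
    pairs
  })
}
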