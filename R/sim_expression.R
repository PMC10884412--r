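## Negative-binomial expression counts for duplicate pairs, with a known
## subset of truly diverged pairs (fixed log2 fold offset on one member).

#' Simulate expression counts for duplicate gene pairs
#'
#' Each duplicate pair shares a lognormal base mean per tissue; a fraction
#' `degp_fraction` of pairs is truly diverged, in which case one random
#' member's mean is shifted by `degp_log2_offset` log2 units in every
#' tissue. Counts are negative-binomial with dispersion `nb_dispersion`
#' (Poisson when 0), with `n_replicates` independent replicates per tissue.
#'
#' @param truth a `sim_truth`, or a data.frame of pairs with columns
#'   `gene_a`, `gene_b` (paralog pairs; for a `sim_truth` the within-species
#'   WGT pairs of the first descendant are used)
#' @param config a [sim_config()]
#' @param n_replicates,n_tissues override the config design if given
#' @return a list of class `count_matrix`: `counts` (genes x samples integer
#'   matrix), `samples` (data.frame with `sample`, `tissue`, `replicate`),
#'   `pairs` (the pair table), and `truth_degp` (gene-pair ids of truly
#'   diverged pairs)
#' @export
simulate_expression_counts <- function(truth, config,
                                       n_replicates = config$n_replicates,
                                       n_tissues = config$n_tissues) {
  pairs <- if (inherits(truth, "sim_truth")) {
    p <- truth$pairs[truth$pairs$type == "wgt_paralog", , drop = FALSE]
    p <- p[p$species_a == p$species_a[1], , drop = FALSE]
    # two-copy groups only: each gene then has exactly one simulated mean
    tab <- table(p$anc_gene)
    p <- p[p$anc_gene %in% names(tab)[tab == 1L], , drop = FALSE]
    p[, c("gene_a", "gene_b")]
  } else truth[, c("gene_a", "gene_b")]
  if (anyDuplicated(c(pairs$gene_a, pairs$gene_b))) {
    stop("pairs must be disjoint: a gene may appear in one pair only",
         call. = FALSE)
  }
  stopifnot(n_replicates >= 1L, n_tissues >= 1L)
  with_seed(child_seed(config$seed, 404L), {
    n_pairs <- nrow(pairs)
    genes <- c(rbind(pairs$gene_a, pairs$gene_b))
    tissues <- paste0("tissue", seq_len(n_tissues))
    samples <- expand.grid(replicate = seq_len(n_replicates),
                           tissue = tissues, stringsAsFactors = FALSE)
    samples <- samples[, c("tissue", "replicate")]
    samples$sample <- paste0(samples$tissue, ".rep", samples$replicate)
    is_degp <- runif(n_pairs) < config$degp_fraction
    shifted_member <- sample(1:2, n_pairs, replace = TRUE)
    fold <- 2^config$degp_log2_offset
    counts <- matrix(0L, nrow = 2L * n_pairs, ncol = nrow(samples),
                     dimnames = list(genes, samples$sample))
    size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
    for (t in seq_len(n_tissues)) {
      base <- rlnorm(n_pairs, config$expr_mean_log, config$expr_sd_log)
      mu_a <- base; mu_b <- base
      mu_a[is_degp & shifted_member == 1L] <-
        base[is_degp & shifted_member == 1L] * fold
      mu_b[is_degp & shifted_member == 2L] <-
        base[is_degp & shifted_member == 2L] * fold
      mu <- c(rbind(mu_a, mu_b))
      for (r in seq_len(n_replicates)) {
        col <- (t - 1L) * n_replicates + r
        counts[, col] <- if (is.finite(size)) {
          rnbinom(length(mu), mu = mu, size = size)
        } else rpois(length(mu), mu)
      }
    }
    storage.mode(counts) <- "integer"
    pair_id <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
    out <- list(counts = counts, samples = samples, pairs = pairs,
                truth_degp = pair_id[is_degp])
    class(out) <- "count_matrix"
    pk_log("simulate_expression_counts", n_pairs = n_pairs,
           n_tissues = n_tissues, n_replicates = n_replicates,
           degp_fraction = config$degp_fraction)
    out
  })
}
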