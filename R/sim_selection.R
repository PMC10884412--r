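## Polymorphism/divergence generator under a gamma DFE with optional
## adaptive divergence; per-gene resolution so gene bootstrap is possible.

#' Simulate folded SFS and divergence data for one copy class
#'
#' Per-gene zero-fold (nonsynonymous) and four-fold (synonymous) folded
#' site frequency spectra are drawn Poisson from the Poisson-random-field
#' expectation: synonymous sites are neutral, nonsynonymous sites mix over
#' a gamma distribution of deleterious `|Nes|`. Divergence counts are
#' Poisson with the nonsynonymous expectation reduced by the mean fixation
#' rate under the DFE and inflated by the adaptive fraction `alpha_true`
#' (adaptive substitutions contribute `alpha/(1-alpha)` of the non-adaptive
#' expectation).
#'
#' @param config a [sim_config()]; `dfe_shape`, `dfe_mean_nes`,
#'   `alpha_true`, `theta_site`, `div_neutral`, `n_chrom_sampled` set the
#'   regime
#' @param n_genes_per_class number of genes to simulate
#' @param copy_class label attached to the output (1, 2 or 3)
#' @param L0,L4 zero-fold and four-fold sites per gene
#' @param seed optional seed override (defaults to the config seed)
#' @return a list of class `selection_input`: per-gene table `genes`
#'   (`gene_id`, `L0`, `L4`, `Pn`, `Ps`, `Dn`, `Ds`), per-gene folded SFS
#'   arrays `sfs0` and `sfs4` (genes x classes), pooled spectra, `n_chrom`,
#'   `copy_class`, and the generating truth
#' @export
simulate_selection_data <- function(config, n_genes_per_class = 500L,
                                    copy_class = 1L, L0 = 900L, L4 = 300L,
                                    seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dfe_shape <= 0) stop("dfe_shape must be > 0", call. = FALSE)
  if (config$n_chrom_sampled < 2L) stop("n_chrom_sampled must be >= 2",
                                        call. = FALSE)
  with_seed(child_seed(seed, 505L + copy_class), {
    n <- config$n_chrom_sampled
    nf <- n %/% 2L
    ng <- n_genes_per_class
    neutral_shape <- fold_sfs_vector(1 / seq_len(n - 1L))
    ns_shape <- dfe_mixture_shape(config$dfe_shape, config$dfe_mean_nes, n)
    e4 <- config$theta_site * L4 * neutral_shape
    e0 <- config$theta_site * L0 * ns_shape
    sfs4 <- matrix(rpois(ng * nf, rep(e4, each = ng)), ng, nf)
    sfs0 <- matrix(rpois(ng * nf, rep(e0, each = ng)), ng, nf)
    fbar <- dfe_mean_fixation_rate(config$dfe_shape, config$dfe_mean_nes)
    eDs <- config$div_neutral * L4
    eDn <- config$div_neutral * L0 * fbar / (1 - config$alpha_true)
    genes <- data.frame(gene_id = sprintf("cls%d_g%04d", copy_class,
                                          seq_len(ng)),
                        L0 = L0, L4 = L4,
                        Pn = rowSums(sfs0), Ps = rowSums(sfs4),
                        Dn = rpois(ng, eDn), Ds = rpois(ng, eDs),
                        stringsAsFactors = FALSE)
    out <- list(genes = genes, sfs0 = sfs0, sfs4 = sfs4,
                pooled_sfs0 = colSums(sfs0), pooled_sfs4 = colSums(sfs4),
                n_chrom = n, copy_class = copy_class,
                truth = list(dfe_shape = config$dfe_shape,
                             dfe_mean_nes = config$dfe_mean_nes,
                             alpha_true = config$alpha_true,
                             theta_site = config$theta_site,
                             fbar = fbar))
    class(out) <- "selection_input"
    pk_log("simulate_selection_data", copy_class = copy_class,
           n_genes = ng, n_chrom = n,
           dfe_shape = config$dfe_shape, mean_nes = config$dfe_mean_nes,
           alpha_true = config$alpha_true)
    out
  })
}

# Rebuild a selection_input from a gene index vector (bootstrap resample).
subset_selection_input <- function(input, idx) {
  out <- input
  out$genes <- input$genes[idx, , drop = FALSE]
  out$sfs0 <- input$sfs0[idx, , drop = FALSE]
  out$sfs4 <- input$sfs4[idx, , drop = FALSE]
  out$pooled_sfs0 <- colSums(out$sfs0)
  out$pooled_sfs4 <- colSums(out$sfs4)
  out
}
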