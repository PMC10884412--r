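#' Simulation configuration
#'
#' Builds the configuration object that drives every synthetic-data
#' generator. Defaults reproduce the study conditions of the pipeline's
#' reference system: an eight-chromosome ancestral karyotype triplicated by
#' a whole-genome triplication (WGT), two descendant lineages, a gene-family
#' WGD retention rate of 0.2, and four-tissue / three-replicate expression
#' sampling.
#'
#' @param seed master seed; every stochastic generator derives its stream
#'   from it
#' @param n_anc_chromosomes ancestral haploid chromosome number (default 8,
#'   the pre-WGT proto-chromosome count of the reference system)
#' @param n_anc_genes genes on the ancestral genome
#' @param wgt_multiplier genome multiplication factor (3 = triplication)
#' @param loss_prob per-copy, per-lineage probability that a duplicated copy
#'   is fractionated away (every ancestral gene keeps at least one copy)
#' @param bias subgenome fractionation bias in `[0, 1]`; 0 = unbiased loss,
#'   1 = maximal spread of per-subgenome loss rates around `loss_prob`
#' @param inv_rate,fus_rate,fis_rate expected numbers of inversions, fusions
#'   and fissions per descendant lineage (Poisson counts)
#' @param ks_wgt_peak,ks_speciation_peak target mean synonymous divergence of
#'   WGT paralog pairs and of cross-lineage ortholog pairs
#' @param ks_sd lognormal spread (sdlog) of pair Ks around its peak
#' @param ka_omega target Ka/Ks ratio used when generating codon pairs
#' @param dfe_shape,dfe_mean_nes gamma distribution of deleterious fitness
#'   effects: shape and mean of |Nes|
#' @param alpha_true adaptive fraction of nonsynonymous divergence
#' @param theta_site population-scaled mutation rate per site (4Ne*mu)
#' @param div_neutral neutral (synonymous) divergence per site to the
#'   outgroup used by the selection generator
#' @param n_chrom_sampled sampled chromosomes for the site frequency spectrum
#' @param degp_fraction fraction of duplicate pairs with true expression
#'   divergence
#' @param degp_log2_offset log2 fold-change applied to one member of each
#'   truly diverged pair
#' @param expr_mean_log,expr_sd_log lognormal distribution of per-pair base
#'   expression means
#' @param nb_dispersion negative-binomial dispersion of counts
#'   (`size = 1/dispersion`); 0 gives Poisson counts
#' @param n_tissues,n_replicates expression design (default 4 tissues x 3
#'   biological replicates)
#' @param retention_rate probability that the extra copy created by a WGD on
#'   a gene-family tree is retained (default 0.2)
#' @param gene_length_codons codon length of simulated CDS
#' @return a list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_anc_chromosomes = 8L,
                       n_anc_genes = 2000L,
                       wgt_multiplier = 3L,
                       loss_prob = 0.55,
                       bias = 0,
                       inv_rate = 4,
                       fus_rate = 2,
                       fis_rate = 2,
                       ks_wgt_peak = 0.5,
                       ks_speciation_peak = 0.18,
                       ks_sd = 0.12,
                       ka_omega = 0.2,
                       dfe_shape = 0.4,
                       dfe_mean_nes = 2000,
                       alpha_true = 0.3,
                       theta_site = 0.005,
                       div_neutral = 0.05,
                       n_chrom_sampled = 24L,
                       degp_fraction = 0.6,
                       degp_log2_offset = 2,
                       expr_mean_log = log(200),
                       expr_sd_log = 0.5,
                       nb_dispersion = 0.05,
                       n_tissues = 4L,
                       n_replicates = 3L,
                       retention_rate = 0.2,
                       gene_length_codons = 300L) {
  cfg <- list(seed = stopifnot_count(seed, "seed"),
              n_anc_chromosomes = stopifnot_count(n_anc_chromosomes,
                                                  "n_anc_chromosomes", 1L),
              n_anc_genes = stopifnot_count(n_anc_genes, "n_anc_genes", 1L),
              wgt_multiplier = stopifnot_count(wgt_multiplier,
                                               "wgt_multiplier", 1L),
              loss_prob = stopifnot_prob(loss_prob, "loss_prob"),
              bias = stopifnot_prob(bias, "bias"),
              inv_rate = stopifnot_nonneg(inv_rate, "inv_rate"),
              fus_rate = stopifnot_nonneg(fus_rate, "fus_rate"),
              fis_rate = stopifnot_nonneg(fis_rate, "fis_rate"),
              ks_wgt_peak = stopifnot_nonneg(ks_wgt_peak, "ks_wgt_peak"),
              ks_speciation_peak = stopifnot_nonneg(ks_speciation_peak,
                                                    "ks_speciation_peak"),
              ks_sd = stopifnot_nonneg(ks_sd, "ks_sd"),
              ka_omega = stopifnot_nonneg(ka_omega, "ka_omega"),
              dfe_shape = stopifnot_nonneg(dfe_shape, "dfe_shape"),
              dfe_mean_nes = stopifnot_nonneg(dfe_mean_nes, "dfe_mean_nes"),
              alpha_true = stopifnot_prob(alpha_true, "alpha_true"),
              theta_site = stopifnot_nonneg(theta_site, "theta_site"),
              div_neutral = stopifnot_nonneg(div_neutral, "div_neutral"),
              n_chrom_sampled = stopifnot_count(n_chrom_sampled,
                                                "n_chrom_sampled", 2L),
              degp_fraction = stopifnot_prob(degp_fraction, "degp_fraction"),
              degp_log2_offset = stopifnot_nonneg(degp_log2_offset,
                                                  "degp_log2_offset"),
              expr_mean_log = expr_mean_log,
              expr_sd_log = stopifnot_nonneg(expr_sd_log, "expr_sd_log"),
              nb_dispersion = stopifnot_nonneg(nb_dispersion, "nb_dispersion"),
              n_tissues = stopifnot_count(n_tissues, "n_tissues", 1L),
              n_replicates = stopifnot_count(n_replicates, "n_replicates", 1L),
              retention_rate = stopifnot_prob(retention_rate,
                                              "retention_rate"),
              gene_length_codons = stopifnot_count(gene_length_codons,
                                                   "gene_length_codons", 10L))
  if (cfg$n_anc_genes < cfg$n_anc_chromosomes) {
    stop("n_anc_genes must be >= n_anc_chromosomes", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' Unknown keys are rejected so that a typo in a config file cannot silently
#' fall back to a default.
#'
#' @param path YAML file whose keys match the arguments of [sim_config()]
#' @return a `sim_config`
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, vals)
}
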