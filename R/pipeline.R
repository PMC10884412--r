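## End-to-end orchestration: simulate -> synteny -> Ks -> retention ->
## placement -> expression -> selection, one seed, one manifest.

scenario_distance_matrix <- function(config, noise_sd = 0.03) {
  ks_sp <- config$ks_speciation_peak
  ks_wgt <- config$ks_wgt_peak
  ks_out <- max(2 * ks_wgt, 1.2)
  labs <- c("spA_1", "spB_1", "spA_2", "spB_2", "out_1")
  h <- c(ks_sp / 2, ks_sp / 2, ks_sp / 2, ks_sp / 2, ks_out / 2)
  d <- matrix(0, 5, 5, dimnames = list(labs, labs))
  # additive ultrametric distances on the shared-WGT history
  depth <- function(i, j) {
    if (i == 5 || j == 5) return(ks_out)
    same_sub <- (i <= 2) == (j <= 2)
    if (same_sub) ks_sp else ks_wgt
  }
  rate <- rlnorm(1, 0, 0.2)
  for (i in 1:4) for (j in seq_len(5)[-seq_len(i)]) {
    d[i, j] <- d[j, i] <- depth(i, j) * rate * rlnorm(1, 0, noise_sd)
  }
  d
}

#' Run the full inference chain on simulated data
#'
#' Simulates a triplicated ancestor and two descendants, writes every
#' intermediate in its on-disk format, runs homology filtering, block
#' chaining, Ka/Ks, Ks-peak detection, the block-median Ks filter,
#' retention-group classification, scenario classification and MAPS
#' placement, duplicate expression testing and copy-class selection
#' inference, and reports each stage's result next to the simulator's
#' ground truth.
#'
#' @param config a [sim_config()]
#' @param outdir output directory (created if needed)
#' @param calibration_t speciation age (Mya) assigned to the ortholog Ks
#'   peak for strict-clock dating (default 57.79)
#' @param n_maps_families gene families for the MAPS stage (default 300)
#' @param n_scenario_trees duplicate-topology gene trees to classify
#'   (default 200)
#' @param n_selection_genes genes per copy class for the selection stage
#'   (default 300)
#' @param n_boot bootstrap replicates for dating and MAPS bands
#'   (default 200)
#' @return a list of class `polyrekit_run`: `manifest` (paths, counts,
#'   thresholds per stage) and `report` (per-stage results vs truth)
#' @export
run_end_to_end <- function(config, outdir = tempfile("polyrekit_run"),
                           calibration_t = 57.79, n_maps_families = 300L,
                           n_scenario_trees = 200L,
                           n_selection_genes = 300L, n_boot = 200L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, outdir = outdir, stages = list())
  report <- list()
  stage <- function(name, paths = character(0), ...) {
    manifest$stages[[name]] <<- c(list(paths = paths), list(...))
  }

  ## 1. genomes -------------------------------------------------------
  sim <- simulate_wgt_genomes(config)
  paths <- c(anc = file.path(outdir, "ancestor.genes.tsv"),
             spA = file.path(outdir, "spA.genes.tsv"),
             spB = file.path(outdir, "spB.genes.tsv"))
  write_gene_table(sim$ancestor, paths["anc"])
  write_gene_table(sim$descendants$spA, paths["spA"])
  write_gene_table(sim$descendants$spB, paths["spB"])
  stage("simulate", paths, n_anc_genes = config$n_anc_genes,
        multiplier = config$wgt_multiplier)

  ## 2. homology + synteny -------------------------------------------
  hitsAA <- sim_homology_hits(sim$descendants$spA, sim$descendants$spA,
                              seed = config$seed)
  hitsAO <- sim_homology_hits(sim$descendants$spA, sim$ancestor,
                              seed = config$seed + 1L)
  hpath <- file.path(outdir, "spA_vs_spA.hits.tsv")
  write_homology(hitsAA, hpath)
  fAA <- filter_homology_hits(read_homology(hpath))
  fAO <- filter_homology_hits(hitsAO)
  blocksAA <- chain_collinear_blocks(fAA, sim$descendants$spA,
                                     sim$descendants$spA)
  blocksAO <- chain_collinear_blocks(fAO, sim$descendants$spA,
                                     sim$ancestor)
  depth <- synteny_depth_ratio(
    lapply(blocksAO, function(b) {  # ancestor as reference side
      list(chrom_a = b$chrom_b,
           anchors = data.frame(rank_a = b$anchors$rank_b))
    }), sim$ancestor)
  stage("synteny", hpath, n_blocks_paralog = length(blocksAA),
        n_blocks_outgroup = length(blocksAO),
        modal_depth = depth$modal_depth)
  report$modal_synteny_depth <- depth$modal_depth

  ## 3. Ka/Ks + peaks + dating ---------------------------------------
  cds <- simulate_codon_pairs(sim$truth, config)
  cds_path <- file.path(outdir, "pairs.cds.fasta")
  write_cds_pairs(cds, cds_path)
  ks <- ka_ks_pairs(cds)
  ks_path <- file.path(outdir, "pairs.kaks.tsv")
  write_pairs_ks(ks, ks_path)
  para <- ks[cds$type == "wgt_paralog" & cds$species_a == "spA", ]
  orth <- ks[cds$type == "ortholog", ]
  peaks_para <- detect_ks_peaks(para$Ks[!para$saturated])
  peaks_orth <- detect_ks_peaks(orth$Ks[!orth$saturated])
  wgt_mode <- peaks_para$mode[which.max(peaks_para$weight)]
  calib <- clock_calibration(peaks_orth$mode[which.max(peaks_orth$weight)],
                             calibration_t)
  age <- estimate_wgt_age(wgt_mode, calib,
                          ks_values = para$Ks[!para$saturated],
                          n_boot = n_boot, seed = config$seed)
  stage("ks", c(cds_path, ks_path), n_pairs = nrow(ks),
        wgt_peak_mode = wgt_mode, orth_peak_mode = calib$ks_orth_peak,
        age_mya = age$age_mya)
  report$ks <- list(wgt_peak_mode = wgt_mode,
                    true_wgt_peak = config$ks_wgt_peak,
                    orth_peak_mode = calib$ks_orth_peak,
                    true_orth_peak = config$ks_speciation_peak,
                    wgt_age_mya = age$age_mya, age_ci = age$ci_mya)

  ## 4. retention ------------------------------------------------------
  retained <- block_median_ks_filter(blocksAA, ks)
  graph <- build_retention_graph(retained, sim$descendants$spA$gene_id)
  cls <- classify_retention_groups(graph, species = "spA")
  truth_class <- sim$truth$copy_class$spA
  lay <- sim$descendants$spA
  inferred <- setNames(rep(1L, nrow(lay)), lay$gene_id)
  lk <- group_lookup(cls$groups)
  inferred[lk$gene] <- lk$copy_class
  true_per_gene <- truth_class[match(lay$anc_gene,
                                     sim$truth$copy_class$anc_gene)]
  acc <- mean(inferred[lay$gene_id] == true_per_gene)
  rg_path <- file.path(outdir, "spA.retention_groups.tsv")
  write.table(cls$groups, rg_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  stage("retention", rg_path,
        class_counts = paste(cls$class_counts, collapse = "/"),
        accuracy = acc)
  report$retention <- list(class_counts = cls$class_counts,
                           truth_counts = table(factor(truth_class,
                                                       levels = 1:3)),
                           per_gene_accuracy = acc)

  ## 5. placement ------------------------------------------------------
  t_wgt_extra <- 10.03  # outgroup split minus ingroup split
  sp_tree <- ape::read.tree(text = sprintf(
    "(out:%f,(spA:%f,spB:%f):%f);", calibration_t + t_wgt_extra,
    calibration_t, calibration_t, t_wgt_extra))
  scen <- with_seed(child_seed(config$seed, 909L), {
    trees <- lapply(seq_len(n_scenario_trees), function(i) {
      build_nj_tree(scenario_distance_matrix(config), outgroup = "out_1")
    })
    count_wgt_scenarios(trees, ingroup_species = c("spA", "spB"),
                        outgroup_species = "out")
  })
  wgd_node <- ape::getMRCA(sp_tree, c("spA", "spB"))
  pos_trees <- simulate_gene_family_trees(sp_tree, wgd_node = wgd_node,
                                          retention_rate =
                                            config$retention_rate,
                                          n_families = n_maps_families,
                                          seed = config$seed)
  null_trees <- simulate_gene_family_trees(sp_tree, wgd_node = NULL,
                                           n_families = n_maps_families,
                                           seed = config$seed + 1L)
  obs_maps <- maps_percentages(pos_trees, sp_tree)
  null_maps <- maps_percentages(null_trees, sp_tree)
  null_sims <- maps_bootstrap(null_maps, n_reps = n_boot,
                              seed = config$seed + 1L)
  pos_sims <- maps_bootstrap(obs_maps, n_reps = n_boot,
                             seed = config$seed + 2L)
  cmp <- compare_maps_to_simulations(obs_maps, null_sims, pos_sims)
  stage("placement", character(0),
        scenario_counts = paste(scen, collapse = "/"),
        maps = paste(round(obs_maps$percentage, 2), collapse = "/"))
  report$placement <- list(scenario_counts = scen, maps = obs_maps,
                           comparison = cmp)

  ## 6. expression -----------------------------------------------------
  cm <- simulate_expression_counts(sim$truth, config)
  cm_path <- file.path(outdir, "spA.counts.tsv")
  write_counts(cm, cm_path)
  tests <- test_duplicate_groups(cm)
  degp <- summarize_degp(tests)
  recovered <- mean(degp$per_tissue$fraction)
  stage("expression", cm_path, n_pairs = nrow(cm$pairs),
        degp_fraction = recovered)
  report$expression <- list(per_tissue = degp$per_tissue,
                            n_all_tissue = length(degp$all_tissue_pairs),
                            recovered_fraction = recovered,
                            true_fraction = length(cm$truth_degp) /
                              nrow(cm$pairs))

  ## 7. selection ------------------------------------------------------
  sel <- simulate_selection_data(config, n_selection_genes, copy_class = 1L)
  sfs_path <- file.path(outdir, "class1.sfs.tsv")
  write_sfs(sel$pooled_sfs0, sel$pooled_sfs4, sfs_path)
  fit <- fit_gamma_dfe(sel)
  ada <- estimate_alpha_omega_a(fit, sel, n_boot = 0L)
  g <- sel$genes
  fi <- fixation_index(sum(g$Dn), sum(g$Ds), sum(g$Pn), sum(g$Ps))
  stage("selection", sfs_path, dfe_shape = fit$shape,
        mean_nes = fit$mean_nes, alpha = ada$alpha)
  report$selection <- list(dfe_shape = fit$shape,
                           true_shape = config$dfe_shape,
                           dfe_mean_nes = fit$mean_nes,
                           true_mean_nes = config$dfe_mean_nes,
                           bin_props = fit$bin_props,
                           alpha = ada$alpha,
                           true_alpha = config$alpha_true,
                           omega_a = ada$omega_a, FI = fi$FI)

  manifest$config <- unclass(config)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out <- list(manifest = manifest, report = report, manifest_path = mpath)
  class(out) <- "polyrekit_run"
  out
}

#' @export
print.polyrekit_run <- function(x, ...) {
  r <- x$report
  cat("polyrekit end-to-end run\n")
  cat(sprintf("  modal synteny depth vs ancestor: %d\n",
              r$modal_synteny_depth))
  cat(sprintf("  Ks peaks: WGT %.3f (true %.2f), ortholog %.3f (true %.2f)\n",
              r$ks$wgt_peak_mode, r$ks$true_wgt_peak, r$ks$orth_peak_mode,
              r$ks$true_orth_peak))
  cat(sprintf("  WGT age: %.1f Mya [%.1f, %.1f]\n", r$ks$wgt_age_mya,
              r$ks$age_ci[1], r$ks$age_ci[2]))
  cat(sprintf("  retention classes (1/2/3): %s (truth %s), accuracy %.3f\n",
              paste(r$retention$class_counts, collapse = "/"),
              paste(r$retention$truth_counts, collapse = "/"),
              r$retention$per_gene_accuracy))
  cat(sprintf("  scenarios shared/lineage/unresolved: %s\n",
              paste(r$placement$scenario_counts, collapse = "/")))
  cat(sprintf("  DEGP fraction: %.3f (true %.3f)\n",
              r$expression$recovered_fraction, r$expression$true_fraction))
  cat(sprintf("  DFE shape %.3f (true %.2f), alpha %.3f (true %.2f)\n",
              r$selection$dfe_shape, r$selection$true_shape,
              r$selection$alpha, r$selection$true_alpha))
  invisible(x)
}
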