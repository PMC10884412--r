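# polyrekit

Inference tools for the **polyploidization–rediploidization** cycle in plant
genomes: detecting an ancient whole-genome multiplication (duplication or
triplication) from synteny and synonymous divergence, placing it on a species
tree, dating it, and characterising what happened afterwards — fractionation
into one/two/three-copy retention groups, expression divergence between the
surviving duplicates, and copy-number-stratified natural selection.

The package is aimed at comparative genomicists working on lineages such as
the Lythraceae mangroves, where a shared whole-genome triplication (WGT)
shortly before a speciation leaves a characteristic joint signature: a 3:1
synteny ratio against an outgroup, a recent Ks peak, mixed-species duplicate
clades in gene trees, and a burst of shared duplications at one species-tree
node. Every stage of the chain is driven and validated by a built-in
genome-evolution simulator with full ground truth, so the whole pipeline is
testable by parameter recovery without any deposited data.

## What is implemented

| Stage | Core idea |
|---|---|
| `simulate_wgt_genomes()` and friends | triplicate an ancestor, split into two lineages, fractionate (per-copy Bernoulli loss, every gene keeps ≥1 copy), rearrange (inversion/fusion/fission), with a replayable event log |
| `filter_homology_hits()`, `chain_collinear_blocks()` | homology filters (identity ≥ 30%, e-value < 1e−10, coverage ≥ 30%) and gap-penalised longest-collinear-chain DP, blocks of ≥ 5 anchors |
| `ng86_ka_ks()`, `detect_ks_peaks()`, `block_median_ks_filter()` | Nei–Gojobori (1986) Ka/Ks with Jukes–Cantor correction and minimal-pathway counting; Gaussian-mixture Ks peaks on log-Ks with BIC; block median Ks 0.2–1.0, pair Ks ≤ 1.26 |
| `build_retention_graph()`, `classify_retention_groups()` | connected components of the Ks-filtered paralog graph → one/two/three-copy retention groups, outgroup anchoring |
| `classify_wgt_topology()`, `maps_percentages()` | duplicate-topology scenarios (shared vs lineage-specific) and MAPS-style per-node subtree duplication percentages with null/positive simulated bands |
| `pair_exact_test()`, `test_duplicate_groups()` | exact conditional (binomial) test for duplicate expression divergence, Bonferroni per tissue × replicate, three-replicate direction-consistent calls |
| `expected_folded_sfs()`, `fit_gamma_dfe()`, `estimate_alpha_omega_a()` | Poisson-random-field folded SFS, gamma DFE of \|Nes\| by maximum likelihood, adaptive divergence α and ω_a with a 200-replicate gene bootstrap, fixation index, log-ratio constraint/selection effects |
| `ltr_insertion_age()`, `estimate_wgt_age()` | LTR retrotransposon dating (age = K / 2r at r = 1.3e−8/site/yr) and strict-clock event dating from Ks peaks |
| `run_end_to_end()` | one seed, one config, all stages, a JSON manifest and a truth-comparison report |

## Worked example

```r
library(polyrekit)
set_log_level("quiet")
cfg <- sim_config(seed = 42, n_anc_genes = 800)
run <- run_end_to_end(cfg, outdir = tempfile(), n_maps_families = 200,
                      n_scenario_trees = 100, n_selection_genes = 300,
                      n_boot = 50)
print(run)
```

```
polyrekit end-to-end run
  modal synteny depth vs ancestor: 3
  Ks peaks: WGT 0.499 (true 0.50), ortholog 0.178 (true 0.18)
  WGT age: 162.6 Mya [160.5, 164.7]
  retention classes (1/2/3): 416/294/95 (truth 406/299/95), accuracy 0.992
  scenarios shared/lineage/unresolved: 100/0/0
  DEGP fraction: 0.606 (true 0.605)
  DFE shape 0.414 (true 0.40), alpha 0.307 (true 0.30)
```

Reading the output: the simulated descendant covers its unduplicated
ancestor at modal depth 3 (the triplication signature); the duplicate and
ortholog Ks peaks are recovered where the generator put them, and the
strict clock converts the duplicate peak into an age on the calibration
timescale (here the generator's peaks imply an old event; see the vignette
for the clock-consistent setting that reproduces a ~64-Mya triplication);
copy classes match the simulator's truth gene by gene at 99%; every
classified gene tree supports a duplication **before** the two species
diverged; 60.6% of duplicate pairs are called expression-diverged against a
true 60.5%; and the selection stage recovers the gamma-DFE shape and the
adaptive fraction α.

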