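---
title: "Methods: models, parameters and design choices in polyrekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in polyrekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polyrekit implements the inference chain used to establish, place and date
an ancient whole-genome triplication (WGT) and to characterise the
rediploidization that follows it. This vignette is the package's own
account of the underlying models, the parameters that matter, and the
places where the design was genuinely open and a choice had to be made.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The genome-evolution simulator

Every stage consumes inputs that the simulator can generate with ground
truth attached (`simulate_wgt_genomes()` and the other `simulate_*`
functions), so each inference step is validated by parameter recovery.

**History model.** An ancestor with `n_anc_chromosomes` (default 8, a
typical pre-triplication proto-karyotype) and `n_anc_genes` genes is
multiplied by `wgt_multiplier` (default 3). The polyploid then splits into
two descendant lineages which independently (i) fractionate and (ii)
rearrange.

*Fractionation* is per-copy independent Bernoulli loss with probability
`loss_prob` (default 0.55), modulated by a multiplicative subgenome bias
`bias` in [0, 1] (per-subgenome loss rates spread linearly across
`loss_prob`·(1 ± bias)); sampling is conditioned on at least one surviving
copy per ancestral gene, which matches a one/two/three-copy retention-group
universe. The bias default is 0: the degree of biased fractionation is a
free parameter, not an assertion. *Rearrangement* draws Poisson numbers of
inversions, fusions and fissions (`inv_rate`, `fus_rate`, `fis_rate`;
defaults 4/2/2 per lineage) applied in random order; the event log is
recorded and `replay_rearrangements()` reproduces each descendant exactly
from the ancestor, the survival matrix and the log (tested).

**Sequence divergence.** True pair-level Ks is lognormal around the event
peak: `ks_wgt_peak` (default 0.5) for WGT paralogs, `ks_speciation_peak`
(default 0.18) for cross-lineage orthologs, spread `ks_sd` (sdlog, default
0.12) — a unimodal peak shape without modelling rate heterogeneity.
`simulate_codon_pairs()` realises a pair as an ancestral CDS plus Poisson
numbers of synonymous and nonsynonymous substitution events. Ancestral
codons are drawn from six fourfold-degenerate families (GGN, GCN, GTN,
CCN, TCN, ACN): within this codon universe every third-position change is
a genuine four-state neutral site and every single-nucleotide
first/second-position move between families is nonsynonymous and
stop-free, so NG86 site counts are exactly S = 1 and N = 2 per codon and
the Jukes–Cantor correction inverts the mutation process without bias.
Targets implying an expected synonymous p-distance ≥ 0.70 (approaching the
3/4 ceiling) are rejected with an error rather than clamped.

**Expression.** `simulate_expression_counts()` gives each two-copy
duplicate pair a shared lognormal base mean per tissue
(`expr_mean_log = log(200)`, `expr_sd_log = 0.5`); a fraction
`degp_fraction` (default 0.6, the neighbourhood reported for
WGT-duplicate divergence in the motivating system) is truly diverged, one
random member shifted by `degp_log2_offset` (default 2) log2 units in
every tissue. Counts are negative-binomial with dispersion
`nb_dispersion` (default 0.05; 0 gives the Poisson limit), with 4 tissues
× 3 replicates by default.

**Selection.** `simulate_selection_data()` draws per-gene folded spectra
Poisson from the Poisson-random-field expectation (Section 5): four-fold
sites neutral at `theta_site` (default 0.005/site), zero-fold sites mixed
over a gamma DFE (`dfe_shape` 0.4, `dfe_mean_nes` 2000 — a typical plant
regime with most mutations strongly deleterious). Divergence is Poisson at
`div_neutral` (0.05/site) for synonymous sites; nonsynonymous divergence
is reduced by the DFE's mean relative fixation rate and inflated so a
fraction `alpha_true` (default 0.3) is adaptive. Population size is
constant; there is no demographic epoch, no linkage, and spectra are
unpolarized by construction.

**What passing tests do and do not show.** The generator matches the
assumptions of the estimators downstream (binomial sampling of duplicate
reads given pair totals in the Poisson limit, PRF independence of sites,
strict-clock rates, genuinely fourfold-degenerate synonymous sites). Real
data violate all of these to some degree — overdispersed counts, linked
selection, rate heterogeneity, biased codon usage — so recovery here
demonstrates correctness of the implementations, not robustness to model
misspecification.

## 2. Synteny: filtering, chaining, depth, karyotype arithmetic

Homology hits are kept when identity ≥ 30, e-value **strictly** below
1e−10, and both per-hit coverages ≥ 0.30 (coverage is per hit, computed as
alignment length over sequence length from `-outfmt "6 std qlen slen"`
input).

`chain_collinear_blocks()` is a weighted longest-collinear-chain dynamic
program per chromosome pair and orientation. Anchor score is
bitscore/`score_scale` (default 100); a chain pays `gap_penalty` (default
0.5) per skipped rank unit on either genome, consecutive anchors may be at
most `max_gap` (default 25) ranks apart, and a block needs at least
`min_genes = 5` anchors. The DP carries a capped anchor-count dimension so
the count constraint is exact; blocks are extracted best-first and each
anchor is used at most once. Ties resolve to the higher bitscore sum, then
the lexicographically first anchor sequence. Adjacent-rank duplicates
hitting one partner gene (tandem arrays) are collapsed to the best hit
first (`collapse_tandem`). The DP is tested for equality against
exhaustive enumeration on toy instances.

Two consequences of max-score chaining are worth knowing. First, the gap
defaults mirror common practice for real genomes; they are knobs, and the
log line records them. Second, a straggler anchor at a block end whose
marginal score is below its gap cost is (correctly) trimmed. For clean
simulated data where fractionation is the only gap process, the
appropriate setting is a generous allowance and a near-zero penalty — the
recovery analyses therefore use `max_gap = 100, gap_penalty = 0.01`, under
which per-gene copy-class recovery against simulator truth is exact
(tested at 10,000 ancestral genes).

`synteny_depth_ratio()` counts, for each reference gene, the distinct
query blocks whose reference-side anchor range covers its rank; a
descendant of an unreduced triplication covers its ancestor at modal depth
3. `expected_ploidy_ladder()` is the purely multiplicative chromosome
expectation (e.g. 7×3×2×2×2 = 168; 8×3 = 24).
`count_rearrangement_events()` is a deliberate lower-bound surrogate, not
a rearrangement-distance solver: per descendant chromosome, `k` distinct
ancestral chromosomes imply `k−1` fusions; an ancestral chromosome spread
over `m` descendants implies `m−1` fissions; sign flips between adjacent
same-ancestor segments are inversion breakpoints. After a WGT the
reference karyotype is the post-WGT one (each subgenome copy counts
separately); with that convention fusions − fissions equals the deficit of
descendant chromosome count, an identity the tests exercise.

## 3. Ka/Ks and Ks-based dating

`ng86_ka_ks()` implements the Nei–Gojobori (1986) counting estimator:
synonymous site fractions per codon averaged over both sequences, observed
differences resolved by equal-weight averaging over all minimal mutational
pathways, Jukes–Cantor correction `K = −3/4·ln(1 − 4/3·p)`. Two
conventions had to be fixed: mutations *to* stop codons count as
nonsynonymous in site tallies, and pathways *through* stop codons are
excluded (if every pathway is blocked, the exclusion is waived). Pairs
with `p ≥ 3/4` are flagged saturated and carry no Ks/Ka; ω is undefined at
Ks = 0. The estimator is the package default rather than a
codon-model/maximum-likelihood method (YN-style ti/tv and codon-frequency
corrections are out of scope for this version); the validation surface is
simulation recovery, and the estimator interface accepts any per-pair Ks
table downstream.

`detect_ks_peaks()` fits Gaussian mixtures to log-Ks (unequal variances),
selecting the component count 1..`max_components` (default 4) by BIC,
with a degenerate constant vector short-circuited to a single peak. The
WGT pair universe is then defined exactly as published: blocks whose
median anchor Ks lies in [0.2, 1.0], minus pairs with Ks > 1.26, minus
saturated pairs.

Dating is a strict molecular clock: a calibration `(ks_orth_peak,
t_calibration)` fixes the rate `2r = ks/t`, and the event age is
`mode/2r`, with a bootstrap over the Ks values feeding the peak for the
interval. The Bayesian relaxed-clock machinery of full phylogenetic dating
is intentionally replaced by this linear estimator; calibration ages are
user inputs. One coherence note: with the package's speciation calibration
(Ks 0.18 at 57.79 Mya) a triplication at ~64 Mya implies a duplicate peak
near 0.2 — at the boundary of the 0.2–1.0 block-median window. The
simulator therefore defaults to `ks_wgt_peak = 0.5` (cleanly inside the
window and well separated from the ortholog peak) for
fractionation/retention analyses, while the dating analysis in
`scripts/acceptance.R` runs a dedicated clock-consistent simulation with
peaks 0.2/0.18. LTR insertion ages use `age = K/(2·1.3e−8)` years, the
two LTRs being identical at insertion; intact elements require 100–3000 bp
LTRs, similarity strictly above 80%, 1–15 kb spacing and a complete
Gag-Pol.

## 4. Retention groups, placement, expression divergence

**Retention groups** are connected components of the graph whose edges are
the Ks-filtered syntenic paralog pairs (igraph underneath; multiplicities
collapsed, self-loops an error). Component sizes 1/2/3 map to copy
classes. Components larger than the multiplication level are flagged and
excluded from class counts: the class universe stops at three and any
splitting rule would be an invention; excluded membership is reported so
users can inspect tandem arrays or filter leakage. Outgroup anchoring
joins each outgroup gene to its group per species and filters to a
copy-class pattern such as (3, 3); orthologs split over two groups in one
species are flagged ambiguous and never counted.

**Placement.** Gene trees may be built internally (`build_nj_tree()`,
neighbor-joining on any distance matrix, rooted on the outgroup) or
supplied as Newick. `classify_wgt_topology()` uses a three-way rule fixed
here explicitly, since partial resolutions can be binned many ways: with
duplicates S1,S2 and L1,L2, mixed-species duplicate clades
((S1,L1),(S2,L2)) → `shared_wgt`; species-monophyletic duplicates →
`lineage_specific`; anything else — missing leaves, multifurcations, other
resolutions — `unresolved`, with no silent polytomy resolution.
`maps_percentages()` replaces full gene-tree/species-tree reconciliation
with species-overlap duplication calling (a node is a duplication if its
child subtrees share a species), which is equivalent on the binary,
complete-taxon families this pipeline feeds it and is deterministic and
dependency-free. A duplication is assigned to the species-tree node whose
clade equals the species union beneath it and supports the node only if
both children cover the whole clade. Null and positive bands come from
bootstrap resampling of per-tree support indicators (statistically
identical to re-running the reconciliation per replicate, ~100× cheaper);
verdicts are: at or below the null median → `no_support`; above the null
band and at or above the positive band's lower edge → `supports_wgd`;
otherwise `ambiguous`.

**Expression divergence.** The exact conditional test conditions on a
pair's read total within a sample, removing library-size normalisation:
under equal expression the count of one member is Binomial(total, p0).
The default null is `p0 = 0.5`; whether the original workflow
length-normalised is unstated, so a CDS-length-corrected null
(`len_a/(len_a+len_b)`) is available but not the default. The Bonferroni
family is all tests actually performed within one tissue × replicate
(all-zero pairs are excluded before counting); the family definition is a
documented choice. A DEGP call requires significance at 5% after
correction in **every** replicate with the same direction of imbalance —
"consistency across three replicates" made precise. Three-copy groups
contribute their three pairwise tests; a group counts as divergent if any
pair is a DEGP. Known limitation: with overdispersed (negative-binomial)
counts the conditional binomial null is anticonservative; calibration
holds exactly in the Poisson limit, which is where the type-I tests run.

## 5. Selection inference

`expected_folded_sfs()` is the Poisson-random-field expectation under
constant population size: density `f(q; S) ∝ (1 − e^{−S(1−q)}) /
((1 − e^{−S}) q(1−q))` per unit θ, binomially sampled to `n_chrom`
chromosomes and folded (the middle class once at even n; S → 0 reduces to
Watterson's θ/i). Numerically the q-integral uses composite
Gauss–Legendre with a boundary-layer split at |S| > 30 (nodes
concentrated within 40/|S| of the relevant endpoint), accurate to ~1e−8
against adaptive quadrature (tested).

`fit_gamma_dfe()` maximises the Poisson likelihood of the pooled zero-fold
folded SFS under a gamma distribution of deleterious |Nes|. The gamma
mixture cannot be handled by fixed polynomial quadrature at this dynamic
range (shape < 1, mean in the thousands): the package tabulates the
folded shape vector on a dense log-|S| grid (log-log cubic splines) and
integrates by a 1024-node equal-probability gamma quantile midpoint rule,
verified against adaptive integration (tested to 1e−6 at study
parameters). Optimisation is multi-start Nelder–Mead on log parameters
(5 starts, reltol 1e−10; ties to best likelihood then smallest shape),
with box rejection outside shape ∈ [1e−3, 100], mean ≤ 1e8.

One identifiability decision matters. With a free nonsynonymous mutation
rate, the strongly deleterious mass and the rate form a near-perfect
likelihood ridge on a folded SFS — mutations at |Nes| ≫ n never segregate,
so only the *deficit* of zero-fold polymorphism against the mutational
expectation pins them down. The default therefore ties
`θ_ns = θ_syn · L0/L4` (equal per-site mutation rate across site classes,
as in the generator and in standard DFE practice); `theta_free = TRUE`
restores the profiled-rate variant for sensitivity analysis.

α follows the classical construction: expected non-adaptive divergence
`E[Dn_na] = Ds·(L0/L4)·E[S/(1 − e^{−S})]` under the fitted DFE,
`α = (Dn − E[Dn_na])/Dn`, `ω_a = α·(Dn/L0)/(Ds/L4)`. Uncertainty is a
gene bootstrap (default 200 replicates): genes resampled with
replacement, spectra and counts re-pooled, DFE refitted (single start,
warm-started at the full-data optimum), α recomputed. The fixation index
is `(Dn/Ds)/(Pn/Ps)` with 0.5 added to every cell when any cell is zero
(flagged), undefined when all four are zero. The constraint and selection
"effects" are closed-form log-ratio surrogates —
`ln((Pn+.5)/(Ps+.5)) − ln(L0/L4)` and
`ln((Dn+.5)/(Ds+.5)) − ln((Pn+.5)/(Ps+.5))` — keeping the familiar effect
names without claiming to be the Bayesian GLMM they stand in for.
Pairwise class contrasts are two-tailed Welch t tests starred at 0.05 and
0.001, with zero-variance pairs flagged degenerate.

## 6. Problem sizes and reproducibility

All randomness flows from one explicit seed per entry point through a
single derived-stream helper; no generator touches global RNG state
outside it, and every simulator is byte-stable under its seed (tested).
The validation suite uses simulation sizes chosen to make Monte-Carlo
error small relative to each tolerance — e.g. 10,000 × 300-codon pairs
for estimator consistency at 2%, 10,000 ancestral genes for exact
copy-class recovery, 2,000 gene families (retention rate 0.2) for the
placement burst, 500 genes × 1,200 sites per class for DFE/α recovery —
while completing on a single CPU in minutes; `run_end_to_end()` defaults
are smaller still, sized for an interactive demonstration.

## 7. Known limitations

- NG86 rather than a codon-model ML estimator; no ti/tv or codon-frequency
  correction (pluggable downstream interface).
- Strict clock dating; no fossil-calibrated Bayesian machinery.
- Constant-size PRF: no demographic nuisance epoch in the DFE fit, matching
  the generator but not real populations.
- The exact conditional expression test is anticonservative under
  overdispersion (see Section 4).
- Rearrangement counting is adjacency arithmetic, a lower bound — not
  GRIMM/DCJ distance.
- The simulator does not model tandem duplication, transposable elements,
  gene conversion, or nucleotide-level neutral background.
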