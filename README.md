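# fluxdiff

Differential metabolic flux analysis from bulk RNA-seq, for two-group
(case/control) skin-biopsy-style cohorts. The package was built around
the question of how lipid and energy metabolism reorganize in
UV-damaged, hyperpigmented skin (solar lentigo versus adjacent normal
skin), where the interesting signal is not a single gene but a
coordinated shift in pathway capacity: which reactions — fatty-acid
elongation, sphingolipid desaturation, phospholipid interconversion,
cholesterol synthesis — can carry more or less flux in lesional tissue.

It is aimed at computational biologists who have a paired lesion/control
expression matrix and a genome-scale metabolic model and want
reaction-level statistics rather than gene-level ones, together with the
co-expression and enrichment companions such an analysis typically
ships with.

## What it computes

**Expression-constrained flux simulation.** For each sample, transcript
abundances (TPM) are pushed through the model's gene-protein-reaction
(GPR) rules to give a per-reaction activity score: `and` (enzyme
complex) takes the minimum over subunits, `or` (isozymes) sums. Within a
sample, activities are normalized by their 95th percentile and clipped
to [0, 1], and each reaction's default flux bounds are scaled by the
result (an E-Flux-style constraint; the percentile normalization makes
the simulation invariant to per-sample rescaling of expression). A
two-stage linear program then produces one flux vector per sample:

1. maximize total throughput `c·v` of the energy subsystems (Citric Acid
   Cycle, Oxidative Phosphorylation, CoA Synthesis, CoA Catabolism,
   Glycolysis and Gluconeogenesis, NAD Metabolism, Fatty Acid Synthesis,
   Fatty Acid Oxidation, Biomass and Maintenance Functions) subject to
   steady state `S·v = 0` and the expression-scaled bounds;
2. fix that optimum and minimize total flux `Σ|v|` (parsimonious FBA
   over split non-negative half-reactions), so each sample gets a
   unique, comparable vector instead of an arbitrary optimal vertex.

**Per-reaction Van der Waerden testing.** For each reaction, the
lesion/control contrast of per-sample fluxes is tested with the Van der
Waerden normal-scores test: pooled values get scores
`A_i = Φ⁻¹(R_i/(N+1))` (mid-ranks for ties), the statistic is
`T = Σ_{i∈lesion} A_i`, and the two-sided p-value comes from full
enumeration of all `C(N, n)` group assignments when that is feasible
(3432 assignments for the 7-vs-7 design; exact, no approximation error)
or from the normal reference with the exact permutation variance
`Var(T) = n_a n_b ΣA² / (N(N−1))` otherwise. Benjamini–Hochberg
correction runs across the tested (non-degenerate) reactions.

**Co-expression and enrichment companions.** Consensus k-means
clustering of per-pair log2 fold-change profiles (median-centered, 30
subsampling repetitions, k = 2..10, k-means++ with restarts) yields a
consensus matrix used both to pick a stable k (PAC criterion) and as a
co-expression similarity whose thresholded edges form gene networks;
plus offline STRING-style PPI ingestion with topology summaries, and
hypergeometric over-representation of GMT gene sets.

**Synthetic cohorts with an answer key.** A generator emulates the
paired 7-vs-7 design: negative-binomial counts, shared per-patient
lognormal factors, recorded transcript lengths for TPM, and planted
fold changes on enzyme genes. `make_gold_standard()` derives the
expected flux direction per reaction from the planted effects and the
model's GPRs, enabling end-to-end parameter-recovery evaluation against
a bundled toy model whose sentinel reactions reuse BiGG-style ids
(`DHCRD2`, `FAEL183`, `SQLEr`, `PSDm_hs`, ...).

## Worked example

Simulate a 7-vs-7 cohort on the toy model with the default planted
effects (0.25× knockdown of the genes gating `DHCRD2` and `FAEL183`,
4× upregulation of the gene gating `PSDm_hs`), then run the flux arm:

```r
library(fluxdiff)

model  <- build_toy_model()
design <- toy_cohort_design(model, seed = 42)
cohort <- generate_counts(design)
tpm    <- counts_to_tpm(cohort$counts, cohort$lengths)
fit    <- simulate_cohort(model, tpm, samples = cohort$samples)
dft    <- differential_flux(fit)
glance(dft)
#> # A tibble: 1 × 6
#>   n_reactions n_tested n_significant  n_up n_down alpha
#>         <int>    <int>         <int> <int>  <int> <dbl>
#> 1          37       35             9     3      6  0.05
```

Nine reactions are flagged at FDR < 0.05: the three planted sentinels
and, for each, its stoichiometrically coupled source and demand steps
(a linear branch forces identical flux along the chain). All carry the
exact-enumeration floor p = 2/3432 ≈ 0.00058 — complete group
separation:

```r
dplyr::filter(dft, significant)[, c("reaction", "mean_lesion",
                                    "mean_control", "p", "direction")]
#>   reaction    mean_lesion mean_control        p direction
#> 1 SRC_ps           33.68          7.67 0.000583        up
#> 2 PSDm_hs          33.68          7.67 0.000583        up
#> 3 DM_pe            33.68          7.67 0.000583        up
#> 4 SRC_dhcer         0.362         1.19 0.000583      down
#> 5 DHCRD2            0.362         1.19 0.000583      down
#> 6 DM_cer            0.362         1.19 0.000583      down
#> 7 SRC_lnlccoa       2.04          8.49 0.000583      down
#> 8 FAEL183           2.04          8.49 0.000583      down
#> 9 DM_dlnlcg         2.04          8.49 0.000583      down
```

So the phosphatidylserine-decarboxylase branch (`PSDm_hs`) gains
capacity in the lesion group while the dihydroceramide-desaturase
(`DHCRD2`) and fatty-acyl-CoA-elongation (`FAEL183`) branches lose it —
exactly the planted ground truth, with no false flags here. The
expression arm and enrichment agree:

```r
det <- de_table(tpm, cohort$samples)
de_filter(det)
#> [1] "DEGS1_toy"  "ELOVL5_toy" "PISD_toy"

sets <- read_gmt(system.file("extdata", "toy_gene_sets.gmt",
                             package = "fluxdiff"))
hypergeom_ora(de_filter(det), sets, universe = tpm$gene)
#> # A tibble: 5 × 6
#>   set              set_size overlap        p     fdr outside_universe
#> 1 sphingolipid_toy        3       2 0.000617 0.00308                0
#> 2 phospholipid_toy        3       1 0.0520   0.130                  0
#> 3 cholesterol_toy         2       0 1        1                      0
#> 4 energy_core_toy        12       0 1        1                      0
#> 5 decoy_toy               5       0 1        1                      0
```

`autoplot(dft)` draws the volcano-style flux contrast;
`consensus_cluster()` + `autoplot()` the consensus heatmap;
`run_pipeline(pipeline_config(seed = 1))` executes the whole thing —
expression → flux → differential flux and expression → clustering /
networks — writing provenance-stamped TSVs and a run report. A thin
command-line wrapper with subcommands (`simulate-data`, `run-flux`,
`diff-flux`, `cluster`, `ora`, `run-all`) ships at
`inst/cli/fluxdiff-cli.R`.

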