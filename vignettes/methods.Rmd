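---
title: "Differential metabolic flux from expression: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential metabolic flux from expression: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxdiff)
```

This vignette explains the models behind `fluxdiff`, the assumptions
they make, the parameters that matter, and the design decisions taken
where the methodology was genuinely open. The companion README shows
the worked example; here we explain *why* the pieces look the way they
do.

## The scientific setting

The package targets paired two-group transcriptome designs — in the
motivating application, solar-lentigo lesions versus adjacent normal
skin from the same patients (seven pairs) — where the quantity of
interest is reaction-level metabolic capacity rather than gene-level
expression. Expression changes in enzyme genes are propagated onto a
genome-scale metabolic model, per-sample flux distributions are
simulated under those constraints, and reactions whose flux differs
between groups are identified with a rank-based test. In parallel, the
same fold-change profiles feed a consensus-clustering co-expression
analysis, and gene-set over-representation summarizes the differential
expression.

## Expression-constrained flux simulation

### From transcripts to reaction activity

A reaction's gene-protein-reaction (GPR) rule states which gene
products it needs. We evaluate rules against TPM values with the
standard E-Flux-style convention:

* `and` (subunits of one complex) → **minimum** of the children: a
  complex cannot run faster than its scarcest subunit;
* `or` (isozymes) → **sum**: independent enzymes add capacity;
* empty rule, or a rule none of whose genes are measured →
  **unconstrained** (the reaction keeps its default bounds).

Genes missing from the expression table are dropped from `or` branches
and skipped inside `and` branches rather than treated as zero: absence
of evidence about one subunit should not block a reaction whose other
subunits are measured.

The assumption underneath is the usual one for transcriptome-driven
flux methods: transcript abundance is a usable proxy for available
enzyme capacity. It ignores translation, post-translational control,
and metabolite-level regulation; conclusions are therefore about
*transcriptionally licensed* capacity, not measured flux.

### Percentile normalization of bounds

TPM has no natural flux unit, so within each sample we normalize
activities by their 95th percentile (`percentile` parameter, default
0.95, dimensionless) across the constrained reactions and clip at 1:

\[
\hat a_r = \min\!\left(1,\; a_r / q_{95}\right),\qquad
ub_r^{\mathrm{eff}} = ub_r \,\hat a_r,\qquad
lb_r^{\mathrm{eff}} = lb_r \,\hat a_r \ \text{(reversible only)} .
\]

Two consequences drive this choice. First, the simulation becomes
scale-free: multiplying a sample's whole expression vector by any
λ > 0 changes neither \(\hat a\) nor the fluxes (verified to 1e-9 in
the tests). Second, the percentile (rather than the maximum) bounds
the influence of a single outlier transcript on every other reaction's
bounds. The percentile is configuration, not dogma — with very few
constrained reactions it behaves like a maximum.

One subtlety worth stating: lowering the expression of a gene *can*
raise another reaction's effective bound, if the lowered gene anchored
the percentile. Monotonicity holds for the GPR activity itself and for
the affected reaction's own bound, and that is what the test suite
asserts.

### The two-stage linear program

Stage 1 maximizes total throughput of the nine energy subsystems
(Citric Acid Cycle, Oxidative Phosphorylation, CoA Synthesis, CoA
Catabolism, Glycolysis and Gluconeogenesis, NAD Metabolism, Fatty Acid
Synthesis, Fatty Acid Oxidation, Biomass and Maintenance Functions)
subject to steady state and the effective bounds. Every reversible
reaction is split into two non-negative half-reactions; the objective
coefficient (+1 by default, per-pathway weights are exposed) applies
to both halves, and reported flux is forward − backward. A composite
equal-weight objective was chosen over lexicographic per-pathway
optimization: "maximize the energy pathways" does not dictate an
ordering, equal weights is the symmetric reading, and the weight
vector is configurable for anyone who disagrees.

Stage 2 fixes the stage-1 optimum (relative tolerance 1e-9) and
minimizes \(\sum_r |v_r|\) — parsimonious FBA. Without it, alternate
optima would make per-sample flux vectors arbitrary vertices of the
optimal face, and a group contrast of arbitrary vertices is
meaningless. With it, futile cycles vanish and equivalent parallel
routes carry no duplicated flux; the remaining degeneracy (how a fixed
total splits across exactly symmetric parallel paths) is documented
and exercised in the tests. Stage-2 minimality is validated against an
independent vertex-enumeration oracle on small models (1e-6).

Both stages run on the package's own bounded-variable primal simplex
with Bland's smallest-index rule. The choice is forced by the problem
class: steady-state flux LPs have *every* equality right-hand side at
zero, the most degenerate basis structure possible, and Dantzig-rule
tableau implementations can select a pivot column whose ratio set is
empty and corrupt the tableau. Bland's rule terminates finitely under
degeneracy, the bounded formulation keeps the box constraints out of
the basis (which stays at the size of the metabolite set), and the
solver is validated in the test suite against vertex-enumeration
oracles on randomized instances, including fully degenerate and
rank-deficient ones. Solver-facing tolerances: reduced-cost and ratio
tolerance 1e-9, steady-state report tolerance 1e-6 (observed residuals
are ~1e-13 on the bundled models). The formulation requires
`lb ≤ 0 ≤ ub` for every reaction — the COBRA default convention —
and models violating it are rejected explicitly rather than shifted.

Fluxes are simulated **per sample**, not per condition mean: the
downstream test needs a within-group flux distribution. A
condition-mean mode would trade statistical interpretability for
stability and is deliberately not the default.

## The Van der Waerden test on fluxes

Per reaction, pooled fluxes are ranked (mid-ranks for ties), scored as
\(A_i = \Phi^{-1}(R_i/(N+1))\), and summed over the lesion group. Two
p-value modes:

* **exact** — full enumeration of all \(\binom{N}{n_a}\) assignments;
  for the 7-vs-7 design that is 3432 assignments, cheap and free of
  approximation error, with a p-value floor of 2/3432 ≈ 5.8e-4;
* **normal** — \(T/\sqrt{\mathrm{Var}(T)}\) against the standard
  normal, with the exact finite-population variance
  \(\mathrm{Var}(T) = n_a n_b \sum A_j^2 / (N(N-1))\).

`auto` mode (the default) enumerates whenever
\(\binom{N}{n_a} \le 2\times10^5\), so the normal approximation only
operates at sizes where it is accurate (max deviation from exact
≈ 0.01 at 10-vs-10; at 5-vs-5 the permutation distribution is so
discrete — atoms of 1/126 — that no continuous reference does better
than ≈ 0.05, which is why small designs are always enumerated).

The test is two-sided (both gains and losses of capacity are
reported); direction is the sign of \(T\). Reactions with identical
flux in every sample (typically structurally blocked ones) are not
tested and are excluded from the Benjamini–Hochberg correction, so a
large blocked fraction cannot dilute the FDR across the informative
reactions. A paired/stratified variant is a noted omission — the
two-sample test mirrors how the flux contrast is defined here, and an
unpaired rank test is also what the expression arm uses by default.

## Differential expression and the significance filter

The expression arm is deliberately simple: TPM normalization
(`TPM_{gi} = (c_{gi}/\ell_g)/\sum_{g'}(c_{g'i}/\ell_{g'})\times 10^6`),
per-gene two-sided Wilcoxon rank-sum p-values (exact at these group
sizes), BH-FDR, log2 fold change of group means with a 1-TPM
pseudocount, and the filter `fdr < 0.05 & |log2FC| > 0.01`, both
strict. No dispersion shrinkage or parametric modeling is attempted —
at seven pairs a calibrated rank test is a defensible, assumption-light
stand-in, and the thresholds are configuration. The |log2FC| > 0.01
default is unusually permissive; it is applied verbatim rather than
second-guessed, and the strictness of both inequalities is pinned by a
boundary-value test.

## Consensus clustering and co-expression networks

Per-gene profiles (per-pair log2 fold changes from
`log2fc_profiles()`) are median-centered per gene, then clustered with
k-means (Euclidean distance, k-means++ seeding, 10 restarts keeping
the best inertia, ≤ 100 iterations) on 30 random 80% gene subsamples
for each k in 2..10. The consensus matrix \(M_k[i,j]\) — the fraction
of co-sampled repetitions in which genes i and j co-clustered — is
reproducible bit-for-bit under a fixed seed, doubles as the
co-expression similarity, and is thresholded (default 0.5) into
network edges. Final assignments cut an average-linkage tree of
\(1 - M_k\).

**Choosing k.** The classical delta-area criterion (relative change in
the area under the consensus CDF, with \(\Delta(k_{\min}) =
A(k_{\min})\)) has a structural pathology when maximized
automatically: its first term is an absolute area, typically ≈ 0.45-0.5
for any data with structure, so argmax gravitates to the smallest k.
On planted 3-cluster data it is a coin flip between 2 and 3. The
default selector is therefore PAC — the proportion of off-diagonal
consensus entries in the ambiguous window (0.1, 0.9) — minimized over
k, with ties going to the **larger** k: a perfectly stable fine
partition makes its coarser merges stable too, so among equally
unambiguous k the finest carries the information. Delta-area remains
available via `select_k(method = "delta-area")`. On structureless
(pure-noise) profiles no selector is meaningful; PAC with
ties-to-larger will then tend to report the top of the k range, which
is a feature to be aware of when interpreting pipeline reports on data
without cluster structure.

## Over-representation analysis

`hypergeom_ora()` is the textbook upper-tail hypergeometric test
\(P(X \ge k)\) with BH correction across sets. The universe defaults
to all genes in the expression matrix — the set of genes that *could*
have been selected — unless the caller supplies one; set members
outside the universe are ignored and counted. Exactness is pinned
against full enumeration of all draws for small universes.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
evaluated; its defaults mirror the motivating design and standard
RNA-seq practice:

| parameter | default | units / rationale |
|---|---|---|
| `n_pairs` | 7 | the paired lesion/control design |
| `nb_dispersion` | 0.1 | NB dispersion α (var = μ + αμ²), a typical bulk RNA-seq value |
| `patient_effect_sd` | 0.2 | log-scale SD of the shared per-patient factor; induces realistic pairing |
| gene lengths | log-uniform 500–5000 nt | TPM needs lengths; drawn once per design and recorded |
| core-energy gene mean | 5000 counts | anchors the per-sample activity percentile |
| sentinel gene mean | 50 counts | keeps normalized activities ≪ 1 so planted up-regulation is not clipped |
| planted effects | 0.25×, 0.25×, 4× | knockdowns on the `DHCRD2`/`FAEL183` gates, upregulation on the `PSDm_hs` gate |

Counts are negative-binomial with a lognormal per-patient factor
shared by the two samples of a pair; planted fold changes multiply the
lesion-group mean. What the generator does **not** emulate: batch
effects beyond pairing, library-preparation biases, gene-gene
correlation beyond the patient factor, zero inflation, and isoform
structure. Passing the recovery tests therefore demonstrates that the
pipeline is correct and well calibrated under its stated noise model —
not that real lesion data will separate as cleanly.

The toy model places each sentinel on its own linear branch
(source → gene-gated sentinel → maintenance demand) that is
stoichiometrically disjoint from the core energy network. This is a
deliberate identifiability device: a planted effect moves exactly one
branch, so recovery and false-flag rates are well defined. It also
means the branch's source and demand steps carry *identical* flux to
the sentinel — the gold standard marks them as coupled, and they are
expected to be flagged together (a real signal, not a false positive).
Real genome-scale models couple reactions far more densely; there,
a significant reaction should be read as "this stoichiometric
neighborhood changed".

The cluster-profile generator (`simulate_cluster_profiles()`) plants
three clusters offset by 3 within-cluster SD per informative
coordinate on **disjoint** 3-coordinate blocks of a 10-dimensional
profile. Disjoint minority blocks are essential: the prescribed
per-gene median centering cancels any offset that occupies the median
of a profile, so offsets on a majority of coordinates would be erased
before clustering. The block design also makes the three centers an
equidistant simplex, which keeps k = 2 maximally unstable — the
regime in which consensus-based k selection is informative.

## Numerical and degenerate-input conventions

* LP: simplex pivot tolerance 1e-10; stage-2 optimum floor
  `opt × (1 − 1e-9)`; steady-state acceptance 1e-6.
* A zero stage-1 optimum short-circuits stage 2 to the zero vector.
* Constant genes get p = 1 in the rank test; constant-flux reactions
  are untested (p = 1, FDR NA, direction "none").
* VdW ties use mid-ranks; exact-mode comparisons use a 1e-12 absolute
  guard on |T| so bit-level noise cannot flip an enumeration count.
* Consensus pairs never co-sampled (possible at very low `reps`) get
  consensus 0 and are counted in `never_cosampled`.
* k-means++ duplicate centers (possible under heavy ties) are jittered
  by 1e-8 before Lloyd iterations.
* BH-FDR wraps `stats::p.adjust(method = "BH")`; the suite pins it to
  a brute-force step-up oracle at deviation zero.

## Problem sizes used in the checks

The bundled evaluations run at the study's natural scale: 7-vs-7
cohorts on the ~37-reaction toy model (50 replicates for parameter
recovery), 2000-reaction null panels for test calibration, 60-gene
profiles over 50 seeds for consensus recovery, and 500–10⁴-case
oracle batteries for the exact components. These sizes give stable
rates (binomial SE ≈ 3% at 50 replicates) while keeping a full run in
the minutes range on one CPU; all of them are parameters, not
constants, and scale up directly.

## Known limitations

* Transcript abundance as a capacity proxy (no proteomics, no
  kinetics, no thermodynamic constraints).
* No flux-variability analysis or flux sampling; the parsimonious
  point estimate is the representative vector.
* The unpaired flux test discards pairing information; a stratified
  variant is future work.
* The built-in simplex is dense and unfactorized, comfortable at
  toy-model scale (tens of reactions, milliseconds per solve) but not
  engineered for genuinely genome-scale models; the LP layer is
  isolated behind one function so a sparse industrial solver can be
  dropped in.
* SBML support is a best-effort FBC subset; BiGG-JSON is the primary
  dialect.
* GO/KEGG databases are not bundled; ORA consumes user-supplied GMT
  files, and PPI networks come from offline edge lists, not live
  STRING queries.
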