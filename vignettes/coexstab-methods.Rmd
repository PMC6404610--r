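---
title: "Methods: stability-filtered coexpression networks and eigengene reaction norms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-filtered coexpression networks and eigengene reaction norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coexstab` analyses bulk RNA-seq experiments in which populations with
different evolutionary histories (an ancestor, a lab-adapted control, and
stress-selected lines) are each profiled in two environments (rearing
temperatures) with replication. Its goal is to describe how the
coexpression structure of the transcriptome — not individual genes —
responds to environment and to selection: which gene modules are plastic,
which have evolved new baseline expression, and which have changed their
plastic response itself. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic validation data can and cannot show.

## The pipeline

The fixed stage order is: normalisation, variance-stabilising transform,
variance filtering, surrogate-variable removal, then (a) ordination and
PERMANOVA on samples and (b) network construction, stability filtering,
eigengene statistics and gene-set enrichment on genes. Every step appends
itself to the expression matrix's `transform_log`, so artifacts are
self-describing.

### Preprocessing

Library sizes are removed with median-of-ratios size factors (the
reference set is genes with nonzero counts in all samples). The default
variance-stabilising transform is the shifted log
$v = \log_2(\mathrm{count}/\mathrm{factor} + 1)$, with an Anscombe-style
NB dialect $\log_2(x + 1/(2\alpha))$ available; both are closed-form,
monotone and finite. The variance filter then drops the 40%
(`drop_fraction = 0.40`) of genes with the lowest variance, computed on
the VST scale across all samples — the VST scale is chosen over raw or
normalised counts because it decouples the filter from library size and
mean expression; the filter and the transform are both recorded, never
silently fused.

Latent structure (thaw batches, library preparation, and other unmodelled
sources) is estimated by a two-step residual-SVD procedure: each gene is
regressed on the protected design (population, temperature and, by
default, their interaction), and the top left singular vectors of the
residual matrix in sample space are the surrogate variables. With
`n_sv = "auto"` the dimension is chosen by permutation parallel analysis:
each gene's residual row is permuted independently (B = 20 permutations)
and components whose singular value exceeds the 95th percentile of the
permuted singular values are kept. This is deliberately not the full
iteratively re-weighted SVA: the residual-SVD estimator has a simple,
testable contract (orthonormal columns, recovery of planted batch vectors)
and no tuning loop. Surrogate variables are removed gene-wise by OLS,
keeping each gene's intercept, so re-regressing the output on the
surrogate variables returns coefficients of zero.

### Ordination and PERMANOVA

Sample structure is summarised with Bray-Curtis dissimilarities,
$d(a,b) = \sum_g |x_{ga} - x_{gb}| / \sum_g (x_{ga} + x_{gb})$.
Residual expression can be negative, and Bray-Curtis is defined for
non-negative data, so the matrix is shifted by its global minimum first;
the shift preserves rank structure and is recorded. Non-metric
multidimensional scaling (Kruskal stress-1, default `k = 5`, 20 random
restarts under one seed) embeds the samples; stress of a configuration is
invariant to rigid motions, and scores are reported centred. PERMANOVA
partitions the Gower-centred dissimilarity matrix sequentially (Type-I)
over population, temperature and their interaction, with free permutation
of sample labels and
$p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})$, default
`n_perm = 1000`. With 199 permutations on null data the temperature
rejection rate is calibrated at the nominal 5% (checked in the test
suite over 200 null simulations).

### Signed network and dynamic tree cut

The network is signed: $a_{ij} = ((1 + r_{ij})/2)^\beta$ with Pearson
correlation and $\beta = 5$, so anti-correlated genes are unconnected
rather than connected. Topological overlap
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$,
$\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}$, rewards shared neighbours;
$1 - \mathrm{TOM}$ is clustered with average linkage.

Module detection is a dynamic hybrid cut with the defaults
`cut_height = 0.905`, `deep_split = 2`, `min_cluster_size = 30` and an
unrestricted (branch-crossing) PAM stage. Stage 1 works on the maximal
branches below the cut height. A junction whose two sub-branches each
hold at least `min_cluster_size` leaves is split when each side looks
like a distinct cluster: its *core scatter* — the mean of the lowest
`min_cluster_size` merge heights of the branch, normalised by the
dendrogram height range — must stay below the `deep_split` ceiling
(0.64/0.73/0.82/0.91/0.95 for `deep_split` 0-4) and sit at least the
corresponding minimum gap below the junction height. A junction also
splits whenever deeper structure splits, since a boundary below proves
the junction joins distinct modules. Simple merge-height gaps are *not*
used: outlying genes attach to branches at nearly continuous heights, so
the raw gap at a junction carries no signal. Small children encountered
during the descent are peeled off; they rejoin their branch if it never
splits, and otherwise are left to stage 2. Stage 2 assigns each
unlabelled gene to the module with the smallest average dissimilarity,
but only if that average is below both `cut_height` and the module's
diameter (the largest average within-module dissimilarity of any
member). The diameter bound matters: without it, genes with no real
module membership sit just inside the radius purely because TOM
denominators are small for low-connectivity genes, and they attach
stably.

### Resampling module stability

Replicated designs allow a direct stability check: for each of
`n_resamples = 100` resamples (25 in the scaled validation runs), 4 of
the 6 replicates of every population x temperature cell are kept and the
network is rebuilt with identical parameters. A module $r$ of a
resampled network that contains at least 10% of a full-network module
$f$ marks the genes of $r \cap f$ as a *significant group* of $f$; one
resampled module may credit several full modules. A gene keeps its
full-network label only if it fell in a significant group of that module
in at least 70% of the resamples (with $\ge$ at the boundary: 70 of 100
retains, 69 does not); everything else, including everything the full
network left unassigned, goes to the unassigned bin. The 10% criterion
is measured against the *full* module's size, and credits are binary per
gene and resample. After retention, modules whose eigengenes correlate
at $r > 0.9$ are merged — grouping is by connected components of the
thresholded correlation graph, and because merging changes eigengenes
the procedure recomputes and iterates to a fixed point (one pass is
available by switch; the fixed point makes the operation idempotent).
Finally modules with fewer than 30 genes dissolve, and labels are
renumbered by decreasing size.

### Eigengene statistics and reaction-norm categories

A module's eigengene is the first principal component of its
gene-standardised expression (unit-norm sample scores from the SVD),
oriented to correlate positively with the module's mean standardised
expression so the sign is deterministic. Variance explained is
$100\,\sigma_1^2/\sum\sigma_k^2$. Within the ancestral population, a
two-sample $t$-test (pooled by default, Welch by switch) asks whether
the eigengene differs between environments. Across all populations, a
two-way fixed-effects ANOVA with interaction (Type-I sums of squares,
identical to Type-III on the balanced design; df 1, 3, 3 over 40 for the
4 x 2 x 6 layout) feeds a decision table at $\alpha = 0.05$:

| interaction | temperature | population | category |
|---|---|---|---|
| sig | - | - | evolved or divergent plasticity |
| ns | sig | sig | divergent baseline |
| ns | sig | ns | shared plasticity |
| ns | ns | sig | non-plastic divergence |
| ns | ns | ns | no signal |

Populations with a significant main effect get Tukey HSD contrasts using
the full-model residual mean square and df (pooled across temperatures,
matching the single population effect of the ANOVA), plus a compact
letter display computed from the maximal cliques of the
non-significance graph — two populations share a letter exactly when
their adjusted $p$ exceeds $\alpha$.

### Enrichment

Gene sets arrive as GMT collections, optionally expanded through a
homolog map in which one source gene may map to several target genes
(all homologs are included; shared targets are counted once; unmapped
genes drop out with per-set coverage reported). Enrichment of a set in a
module is the upper-tail hypergeometric probability of the observed
overlap — a one-tailed Fisher test for over-representation — with the
odds ratio $ad/bc$ reported alongside. The universe is the set of genes
that survived preprocessing, i.e. the genes that could have been
assigned, not the whole genome. FDR is controlled with
Benjamini-Hochberg within each collection (all sets of a collection
across all modules share one adjustment), so adding an unrelated
collection never changes existing q-values.

## The synthetic-data generator

Validation uses planted-truth simulation, not the deposited experiment.
The default design mirrors the study layout: 4 populations x 2
temperatures x 6 replicates = 48 samples. Each planted module has a
latent eigengene with cell means
$e(\mathrm{pop}, T) = \tau\,\mathbb{1}[T = 30] + \pi_{\mathrm{pop}} +
\gamma_{\mathrm{pop},T}$ realised per sample with standard-normal
replicate noise, so all effects are in replicate-SD units; the default
archetype effect size is 2. Gene $g$ of a module has log2-scale mean
$\mu_g + \lambda_g e_s + \sum_b w_{gb}\,\mathrm{batch}_{bs} +
\varepsilon_{gs}$ with baselines $\mu_g \sim U(5, 9)$, loadings
$\lambda_g \sim N(0.8, 0.1)$ and noise SD 0.6; background genes have
$\lambda = 0$. Counts are negative binomial (dispersion 0.05) after a
uniform library-size factor in [0.75, 1.33]. The generator draws every
module, the background, and each global component from a named RNG
substream, so adding a module never perturbs another block's values.

Design choices worth knowing:

* **Batch factors are centred within treatment cells** before scaling to
  unit SD. A latent factor drawn freely over 48 samples is randomly
  confounded with the 8-cell design, which makes "the batch" ill-defined
  as a target of recovery; centring makes batch and design orthogonal by
  construction, which is also the situation in which removing batch
  cannot remove design signal.
* **Archetypes are balanced and orthogonal in the recovery benchmark.**
  The benchmark plants five modules (400/400/175/175/50 genes) with
  induced and repressed temperature responses of equal total gene mass
  and orthogonal population patterns. If most planted genes respond in
  one direction, the median-of-ratios reference no longer tracks the
  null genes and normalisation imprints a spurious anti-correlated
  signal on the background — a real compositional artifact that any
  median-based normalisation has, and one reason real designs should
  expect responses in both directions.
* **The divergent-plasticity archetype reverses the response in half the
  populations** (+2 in two populations at 30°, −2 in the other two).
  This is the configuration in which an interaction of 2 SD is actually
  detectable at 6 replicates per cell (noncentrality 48 for the
  3-df interaction test, power > 0.99); a single-cell interaction of the
  same size has power near 0.7 and cannot support a 90% recovery
  requirement.
* **Classification and eigengene validation plant one 50-gene module over
  200 background genes.** The background is not decoration: with no null
  genes, the size-factor median sits inside the module and normalisation
  absorbs the module's shared signal.

What passing these simulations does *not* show: the generator's modules
are cleanly separated blocks with homogeneous loadings, NB noise and at
most a few latent factors. Real transcriptomes have correlated modules,
hub structure, mean-dependent dispersion, and batch effects entangled
with the design; recovery there will be worse than on planted blocks,
and the stability filter's retention rates should be read as
data-specific, not as guarantees.

## Numerical choices and degenerate inputs

* Variance-filter ties at the cutoff resolve by stable input order, and
  exactly $\lceil (1-f) G \rceil$ genes are kept.
* Zero-variance genes are rejected by the network stage by id
  (correlation undefined) rather than silently dropped.
* A TOM denominator of zero (isolated pair) yields overlap 0; the
  diagonal is 1 by convention.
* An exact-fit ANOVA (zero residual mean square) reports $F = \infty$,
  $p = 0$ for saturating effects, $F = 0$, $p = 1$ for absent ones, and
  carries a `degenerate` flag.
* Eigengene orientation falls back to the sign of the largest-magnitude
  score when the module mean is exactly flat.
* The retention boundary uses $\ge$ with a $10^{-9}$ guard against
  floating-point drift in `threshold * n_resamples`.
* Stage seeds derive from one master seed by hashing the stage name into
  a 32-bit substream seed, so any stage can be re-run in isolation and
  results are bit-reproducible end to end.

## Validation scale

The shipped tests and the acceptance script run entirely on generated
data at desk scale: the module-recovery benchmark uses 2,000 genes, 48
samples and 25 resamples; classification and eigengene properties use
100 replicates of a 250-gene dataset; PERMANOVA calibration uses 200
null datasets of 60 genes at a 2 x 2 x 3 design with 199 permutations.
These sizes were chosen to exercise every stage, including the full
resampling loop, while a complete validation run stays in the minutes
range on one CPU.

## Known limitations

* The VST is a closed-form transform, not a fitted dispersion-mean
  curve; for very low counts the anscombe dialect is preferable.
* The surrogate-variable estimator protects the design but, like any
  residual-based method, will absorb module eigengene noise into its
  components when modules are strong; the pipeline therefore applies it
  before network construction only when latent structure is expected.
* PERMANOVA uses free permutation; restricted/residual permutation
  schemes are out of scope.
* The dynamic cut reproduces the hybrid algorithm's behaviour
  (core-scatter splitting, diameter-bounded PAM) but is not a line-level
  port; planted-block recovery, not label-exact agreement with any
  particular implementation, is its contract.
* Tukey letters use maximal cliques; with many groups, several minimal
  letter covers can exist and the display is canonical only up to letter
  order (cliques are lettered by ascending group mean).
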