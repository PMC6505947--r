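---
title: "Partitioning community-assembly processes in penguin gut microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning community-assembly processes in penguin gut microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, numerical choices and design decisions
behind `penguinproc`, and states precisely what the synthetic-data generator
does and does not establish.

## The analysis model

The package operates on a rarefied OTU count table, a rooted phylogeny over
the OTUs, and a two-factor sample design (species chinstrap/gentoo crossed
with stage feeding/moulting).  Four analysis strands share the preprocessed
table:

1. **Composition** — Hellinger-transformed counts
   (`sqrt(count / rowsum)`), Bray–Curtis dissimilarities, NMDS ordination
   with per-group SD ellipses, and PERMANOVA.
2. **Diversity** — Shannon index and richness per sample, compared between
   stages within each species by Welch's t-test.
3. **Taxon-level shifts** — counts aggregated to phylum/family, group means
   as the mean of per-sample proportions, per-taxon Welch tests with
   Benjamini–Hochberg correction.
4. **Assembly processes** — βNTI and RC_bray null models followed by the
   five-way classification (variable selection, homogeneous selection,
   dispersal limitation, homogenizing dispersal, drift).

### βNTI

For samples $i, j$ with within-sample relative abundances $f$ over their
present taxa and patristic distances $d$,

$$\beta\mathrm{MNTD}_{ij} = \tfrac12\Big[\sum_{t \in i} f_{ti}
\min_{u \in j} d(t,u) + \sum_{u \in j} f_{uj} \min_{t \in i} d(u,t)\Big].$$

The null shuffles taxon labels across the tips of the tree pruned to the
taxa observed anywhere in the table (the regional pool is the whole
dataset); one shuffle per iteration is applied to all pairs, and
$\beta\mathrm{NTI} = (\mathrm{obs} - \bar{\mathrm{null}})/\mathrm{sd}_\mathrm{null}$.
Pairs whose null SD collapses to floating-point dust (relative
$\mathrm{sd} \le 10^{-6}\,|\bar{\mathrm{null}}|$, e.g. on a star phylogeny)
are flagged `NaN`, reported, and excluded from summaries.

### RC_bray

Each null community preserves its sample's observed richness $k$ and read
total $N$: $k$ taxa are drawn without replacement with probability
proportional to occupancy (number of samples containing the taxon), each
receives one read, and the remaining $N - k$ reads are multinomial with
probability proportional to the pooled relative abundance restricted to the
drawn taxa.  With $n_\mathrm{null}$ draws,
$RC = 2\big[(\#\{d_\mathrm{null} < d_\mathrm{obs}\} +
\tfrac12\#\{d_\mathrm{null} = d_\mathrm{obs}\})/n_\mathrm{null} -
\tfrac12\big] \in [-1, 1]$.

Two implementation decisions deviate from a literal per-pair reading and are
deliberate:

* Null communities are generated **per sample per iteration** and paired
  within an iteration, rather than independently for every pair.  The
  marginal null distribution of each pair is identical; the cost drops by
  the pair/sample ratio (~24x here).  This mirrors the
  one-shuffle-per-iteration rule used for βNTI.
* Occupancy and pooled abundance come from the **full rarefied table**, not
  per group, so a pair's null reflects the study-wide species pool.

### Classification

Strict inequalities protect the stochastic side: `bnti > +2` variable
selection; `bnti < -2` homogeneous selection; otherwise `rc > +0.95`
dispersal limitation, `rc < -0.95` homogenizing dispersal, else drift.
Boundary values (exactly 2 or 0.95) therefore classify as drift, and a
published "drift" condition that mixes the two thresholds inconsistently is
implemented as $|\beta\mathrm{NTI}| < 2$ and $|RC| \le 0.95$, the only
arithmetically coherent reading.  Group summaries report percentages of
valid (finite-βNTI) within-group pairs; every percentage is an integer
multiple of $100/\binom{n}{2}$, which is the granularity visible in
published tables of this kind.

### PERMANOVA

The squared dissimilarity matrix is Gower-centred,
$G = -\tfrac12 C D^{(2)} C$, and sequential (Type I) sums of squares are
traces of $G$ projected on nested factor designs in the order species,
stage, interaction — the order mirrors the usual results-table layout, and
Type I is the honest choice for the unbalanced 7/6/7/5 design (documented
limitation: term order matters).  p-values use unrestricted permutation of
sample rows with the add-one convention, so the smallest attainable p at
999 permutations is 0.001.  Unrestricted permutation was chosen over
residual-permutation schemes as the simplest defensible scheme for small,
nearly balanced designs; the implementation reproduces `vegan::adonis2`
sums of squares and pseudo-F exactly (verified in the tests).

### NMDS

Kruskal stress-1 is minimized directly:
$S = \sqrt{\sum (\hat d - e)^2 / \sum e^2}$, where $e$ are configuration
distances and $\hat d$ their isotonic (pool-adjacent-violators) regression
on the observed ranks.  Ties are handled by Kruskal's primary approach —
within a tie block the fitted values follow the sorted configuration
distances.  Optimization is BFGS with the analytic gradient (monotone fit
held fixed), from one classical-scaling start plus `n_starts - 1` random
starts (default 20), 300 iterations, relative tolerance `1e-7`; the best
start is kept and the configuration is centred and rotated to principal
axes.  A degenerate all-equal distance matrix yields a warning and a
configuration flagged not-converged.

## The synthetic world

`simulate_study()` emulates a 25-sample, 4-group design (7/6/7/5) with 500
taxa and 20,000 reads per sample — above the default 13,415 rarefaction
depth so the subsampling stage does real work.

* **Phylogeny**: pure-birth (Yule) tree, ultrametric, strictly positive
  branch lengths.
* **Metacommunity**: power-law rank-abundance, exponent 1.2 — strongly
  uneven, like real gut communities dominated by a few taxa.
* **Niche trait**: Brownian motion on the tree (rate `trait_sigma = 1`),
  guaranteeing the phylogenetic signal that the βNTI framework presupposes.
* **Selection regime**: sample $i$ draws reads with weight
  $w_t \propto \mathrm{meta}_t\,
  e^{-(\mathrm{trait}_t - \mathrm{env}_i)^2 / 2\sigma_f^2}$.  Variable
  selection spaces the group's environments evenly across
  $\pm 1.5\,\mathrm{SD(trait)}$ with filter width
  $\sigma_f = 0.4\,\mathrm{SD(trait)}$; homogeneous selection pins all
  environments to the trait median.
* **Dispersal-limited regime**: taxa partitioned into disjoint patches,
  samples draw from their patch mixed with the full pool by `patch_mix`.
* **Host-level drift**: every sample's probabilities are first perturbed as
  $p \sim \mathrm{Dirichlet}(c \cdot w)$ with concentration
  `host_dispersion = 100`.  Without this, replicate multinomial draws of
  13,415 reads are nearly identical (within-group Bray–Curtis ~0.08), which
  no real faecal dataset shows and which an occupancy-based Raup–Crick null
  (mis)reads as homogenizing dispersal.  $c = 100$ gives within-group
  Bray–Curtis around 0.4, mid-range for gut microbiota.  The low-level
  generators (`simulate_neutral()` etc.) default to `dispersion = Inf` —
  pure multinomial — so their distributional contracts stay exact.

These values were fixed once, from realism arguments, before the acceptance
suite was frozen; regime recovery is robust across the neighbourhood
($\sigma_f$ 0.3–0.4, spread 1.5–2.0) rather than a knife-edge.

**What a green test establishes — and what it does not.**  The generator
produces the *mechanisms* (selection on a conserved trait, patch structure,
drift) whose recovery the classification is tested against.  It does not
emulate sequencing error, chimeras, compositional biases of PCR, read-depth
variation, or taxon-specific detection; nor does it attempt to match any
real dataset's taxon identities.  Green regime-recovery tests therefore
establish that the null models and classifier recover known mechanisms at
realistic effect sizes and sample sizes — not that any particular empirical
percentage would be reproduced.

## Numerical and reproducibility choices

* Rarefaction is a true multivariate hypergeometric subsample, drawn in
  canonical (sorted taxon id) order so results are invariant to column
  order; sub-depth samples are dropped with a count, never rescaled.
  Singleton removal (taxa with dataset-wide count 1) precedes rarefaction;
  the literature this follows is silent on the order, so it is fixed and
  documented here.
* Shannon uses natural log by default (`base = "2"` available); group-level
  relative abundances are means of per-sample proportions, matching the
  per-sample t-tests.
* One master seed fans out to stage- and sample-tagged substreams
  (`substream_seed`), so every stage is reproducible independently of
  execution order, and identical config + seed gives byte-identical output
  files (asserted in the tests).
* βMNTD/βNTI inner loops are C++ (`Rcpp`); 999 null iterations over 25
  samples x 500 taxa take a few seconds.
* Weighted βMNTD is the default (the abundance-weighted variant of the
  framework this follows); `weighted = FALSE` gives the presence/absence
  version.

## Known limitations

* Type I (sequential) sums of squares make PERMANOVA term order matter in
  unbalanced designs; the species-first order is fixed and documented.
* The RC_bray null shares draws across pairs within an iteration (see
  above); pair-to-pair null correlations exist but marginal inference per
  pair is unchanged.
* NMDS minimizes a non-smooth objective; with very few points multiple
  starts can still return a local optimum, which is why the stress of the
  best start and a convergence flag are always reported.
* The phylogeny is taken as given; no tree inference is performed, and
  βMNTD requires branch lengths (strict newick mode refuses trees without
  them).
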