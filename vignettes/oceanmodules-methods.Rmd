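---
title: "Methods: co-occurrence modules, assembly mechanisms and drifter transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence modules, assembly mechanisms and drifter transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`oceanmodules` implements an analysis chain for marine prokaryotic amplicon
(ASV) data that (i) infers compositional co-occurrence networks per data
subset, (ii) dissects the global network into modules and validates them
against rewired nulls, (iii) quantifies per-sample community mixing as local
network modularity, (iv) classifies pairwise community assembly mechanisms
with phylogenetic and compositional null models, and (v) links spatial
patterns of mixing to surface-current accumulation estimated from drifter
trajectories via a Markov transport matrix. A synthetic-data generator
provides all inputs with the statistical structure the analysis assumes, so
the full chain is testable offline.

# The models

## Compositional correlation (SparCC)

Amplicon counts are compositional: per-sample totals are arbitrary, so naive
correlations are biased. The SparCC estimator works from log-ratio variances
$t_{ij} = \mathrm{var}\,\log(x_i/x_j)$ and the basis-variance approximation
$M w = t$ with $\mathrm{diag}(M) = p-1$ and off-diagonal 1, giving
correlations $r_{ij} = (w_i + w_j - t_{ij}) / (2\sqrt{w_i w_j})$. Pairs with
$|r|$ above an exclusion threshold (default 0.1) are iteratively removed
from the linear system (default 10 rounds) so a few strongly coupled pairs
do not distort the basis. For exactly three components the system is
determined and has the closed form $w_1 = (t_{12}+t_{13}-t_{23})/2$, which
the tests use as an oracle; below four components the approximation is
degenerate and the function refuses to run.

Fractions are estimated either deterministically with pseudocounts
($(x+1)/\sum(x+1)$, the default) or as Dirichlet posterior draws whose
median correlation over `n_inner_iter` resamplings is returned. Significance
is a plain bootstrap proportion: each ASV's counts are permuted
independently across samples 999 times (destroying co-variation, preserving
marginals) and $p_{ij}$ is the fraction of permutations with $|r|$ at least
as extreme as observed; no add-one correction is applied, so the minimal
attainable p is 0. Rows are put in a canonical (sorted) order before
permuting so p-values are exactly invariant to input sample order.
Benjamini–Hochberg adjustment runs over the upper triangle within each
subset. Edges retained are positive, $r \ge 0.5$ and adjusted $p \le 0.05$;
negative associations are excluded because modules are interpreted as
groups of co-occurring organisms.

## Modules and their validation

Per-subset edge lists (one subset per ocean × size fraction × depth layer)
are unioned into one global undirected simple graph; a pair recurring in
several subsets collapses to one edge carrying the maximum r and the set of
source subsets (the merge rule is a package choice — the provenance
annotation preserves the information needed to revisit it). Modules are
detected by Girvan–Newman edge betweenness on the unweighted graph with the
dendrogram cut at maximum Newman–Girvan modularity
$Q = \sum_c (L_c/m - (d_c/2m)^2)$; clustering is delegated to igraph (the
toolchain convention for this analysis family) while $Q$ itself is
implemented in the package and cross-checked against igraph in the tests.

Module significance uses a rewiring null: each edge endpoint is resampled
uniformly with probability 0.5 (edge count preserved, degrees not),
multi-edges and loops are dropped, the shuffled graph is re-clustered, and
the p-value is the proportion of null modularities at least as large as the
observed one. A degree-preserving double-edge-swap mode is available; the
endpoint mode is the default because the description of the original
procedure ("randomly defining terminal nodes for edges at probability 0.5")
matches endpoint resampling more closely.

## Local structure

A sample's subnetwork is the induced subgraph on the ASVs present in it;
its local modularity is $Q$ of that subgraph under the restriction of the
*global* membership. An edgeless subgraph has no defined $Q$ and is
reported missing rather than zero. Module profiles are read fractions per
module (with an explicit unassigned remainder; an assigned-reads
normalization is available because the figure convention of the source
analyses is ambiguous). The number of modules present uses a 1% read
fraction threshold by default so isolated stray reads do not count as
presence. Richness coupling is ordinary least squares of richness on the
module count with a two-sided slope test. The latitudinal modularity
profile is smoothed with a tricube local-linear smoother (bandwidth = span
× latitude range, span 0.5): `stats::loess` itself is numerically unstable
when most predictor values are exact ties, which transect designs (few
stations, many samples per station) always produce, so the smoother is
implemented directly and evaluated on the observed latitude support.

## Assembly mechanisms

For each sample pair (within ocean × fraction × layer by default):

1. Abundance-weighted βMNTD,
   $\tfrac12\big(\sum_{i\in A} p_i \min_{j\in B} d_{ij} +
   \sum_{j\in B} p_j \min_{i\in A} d_{ij}\big)$, on cophenetic distances.
2. βNTI: z-score of βMNTD against 999 tip-label shuffles of the distance
   matrix. βNTI > +2 → heterogeneous selection; < −2 → homogeneous
   selection.
3. Otherwise the abundance-adjusted Raup–Crick index on Bray–Curtis:
   null assemblies preserve each sample's richness and total abundance,
   drawing species with probability proportional to occurrence frequency
   and placing individuals proportional to pool relative abundance;
   $RC = 2\,(\#\{BC_{null} < BC_{obs}\} + \tfrac12\#ties)/n_{null} - 1$.
   RC > 0.95 → dispersal limitation; RC < −0.95 → homogenizing dispersal;
   the residual class is stochastic drift.

Per-pair seeds derive deterministically from (master seed, pair index), so
classification is independent of evaluation order. Pairs whose communities
have identical taxon membership are degenerate for βNTI (βMNTD is 0 under
every shuffle); the classifier routes them to the compositional test, which
is the appropriate reading — no phylogenetic signal is detectable. Note two
desk-scale caveats established while testing: for minuscule species pools
RC is inflated above −1 by the tie mass of the null (RC = P(tie) − 1 for
identical communities), and |βNTI| > 2 requires communities that occupy a
shallow clade of an otherwise deep, scattered tree — if every module is a
tight clade, random shuffles still find close pairs and the null loses
power.

## Drifter transport

The ocean is gridded into dx × dy cells (0.5° defaults, matching the
study-scale product). Trajectories are cut into non-overlapping consecutive
30-day subtrajectories ("subdivided" is read as a partition, not a sliding
window); start/end cells are counted into $N_{ij}$ and rows normalized to
probabilities. The state space is restricted to visited cells — land never
enters the matrix because no drifter reports from it — and cells observed
only as endpoints become self-absorbing rows. A tracer (uniform unit mass
by default) is advected by right-multiplication per 30-day step; a
simulated year is 12 steps (360 days), keeping step counts integral; the
divergence from 365 days is immaterial at this scale. Mean drifter speed
per cell uses haversine displacements of consecutive 6-h fixes. Station
concentrations average a 10-cell longitudinal window centered on the
station (in-bounds unvisited cells count as zero; cells beyond the grid
edge are dropped from the denominator).

# The synthetic world

The generator emulates the sampling design the analysis assumes: two ocean
basins × three (configurable) size fractions × two depth layers along a
latitudinal gradient, with:

- **Planted niche modules.** Each module is an axis-aligned Gaussian niche
  in (|latitude|, depth, temperature). The default five roles are
  warm-upper (center 10°), cold-upper (50°), a transitional module at 30°,
  and warm/cold lower-epipelagic modules (170 m). Latitude breadth is 8°,
  chosen once so that expected abundance falls below one read a few niche
  widths from the center — reproducing the presence–absence turnover real
  transects show — while warm and cold niches still overlap in the 25–35°
  band. Depth breadth is 20 m so lower-epipelagic ASVs are exact zeros in
  upper-layer samples: same-latitude modules in different layers share
  their latitude kernel, and any leakage across layers correlates them
  spuriously within a layer subset (all-zero columns are harmless — their
  bootstrap p is 1 by construction).
- **Compositional noise.** Expected relative abundance of an ASV is
  proportional to exp(module log-abundance + fixed per-ASV offset (sd 0.5)
  + per-(ASV, sample) noise (sd 0.3) + log niche kernel); counts are drawn
  multinomially at a lognormal sequencing depth (mean 21,791 — the
  study-scale mean — truncated at 1,000 so rarefaction to 8,000 retains
  most samples).
- **Phylogeny.** A random ultrametric tree built directly as a newick
  string; modules flagged `phylo_cluster` become clades of height 0.25 on a
  height-1 tree, others scatter as backbone leaves. This is what gives
  selection scenarios their phylogenetic signal.
- **Drifters.** Forward-Euler advection at 6-h steps in a prescribed field
  whose meridional component converges on ±30° (tanh profile, 10 cm/s
  amplitude), with uniform zonal drift (5 cm/s) and 5 km/step Gaussian
  noise; lifetimes are normal around one year. Deployment boxes sit around
  each basin's stations so tracer fields and station windows overlap.

What a green end-to-end test establishes: that the chain recovers planted
module partitions, locates the planted mixing band by local modularity,
couples module counts to richness, and rank-correlates tracer accumulation
with modularity — *given* niches that are separable on the sampled gradient
and a transport field with genuine convergence zones. What it does not
establish: performance on real data with thousands of ASVs, un-modelled
taxa, seasonal signals, chimeras/contaminants, or realistic circulation —
none of which the generator emulates (ENSO phases, in particular, are
injected as metadata labels, not simulated physics).

# Numerical and design choices

- Abundance-filter thresholds are strict inequalities exactly as printed
  (">0.001%" of all reads, ">1%", ">0.1%"); "at least x% of samples" is ≥
  on the raw fraction with no rounding. The filter runs per ocean basin and
  keeps the union of survivors.
- Rarefaction is without replacement (vegan-style), preserving count
  support; samples below the target depth are dropped.
- Niche-summary z-scores use the population (n-denominator) standard
  deviation — the modules are the entire population of interest; a
  zero-variance parameter yields z = 0 for all modules.
- Weighted UniFrac is normalized:
  $\sum_e l_e |a_e - b_e| / \sum_e l_e (a_e + b_e)$, bounded to [0, 1];
  WPGMA linkage is `hclust(method = "mcquitty")`.
- Ties in maximum |r| during SparCC exclusion and in edge betweenness break
  lexicographically / by igraph's deterministic order, so runs are
  bit-reproducible.
- Every stage derives its own sub-seed from the master seed and a stage
  tag, so adding randomness to one stage never perturbs another; per-pair
  and per-bootstrap seeds keep results order-independent. All derived seeds
  stay below 2^31.
- The pipeline's toy transport grid is 2° (the `grid_spec` default remains
  0.5°): 200 drifters cannot populate a 0.5° global grid.

# Limitations

- SparCC p-values at 999 shuffles bottom out at 0; at study scale a
  permutation add-one correction would be more conservative. The plain
  proportion is kept because that is the procedure being reimplemented.
- The rewiring null's "endpoint resampling at probability 0.5" is one of
  two defensible readings of the original description; the
  degree-preserving mode is exposed for the other.
- βNTI at desk scale (tens of taxa) has limited power; the acceptance
  scenarios document the regimes where the ±2 cutoff is informative.
- The transport matrix assumes regular 6-h fixes and drogued drifters;
  undrogued slip correction is out of scope.
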