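# oceanmodules

Dissecting open-ocean prokaryotic communities into **co-occurrence
modules** — subcommunities of ASVs that share an environmental niche — and
asking how physical mixing by surface currents assembles them. The package
is aimed at microbial ecologists and biological oceanographers who work
with 16S amplicon (ASV) tables along spatial transects and want to go from
counts to (1) validated network modules, (2) per-sample measures of
community mixing, (3) assembly-mechanism classifications, and (4) a
physical null for where currents should accumulate drifting organisms.

## What it computes

| Stage | Method |
| --- | --- |
| Preprocessing | conservative three-criterion abundance filter, rarefaction (8,000 reads), richness, inverse-Simpson ENS, weighted UniFrac + WPGMA, abundance-weighted niche summaries |
| Networks | SparCC compositional correlations per (ocean × size fraction × depth layer) subset, 999-fold bootstrap p-values (BH-adjusted), positive edges with r ≥ 0.5, p ≤ 0.05 |
| Modules | Girvan–Newman edge-betweenness clustering cut at maximum Newman–Girvan modularity `Q = Σ_c (L_c/m − (d_c/2m)²)`; rewiring null test (999 shuffles) |
| Local structure | induced per-sample subnetworks, local Q under the global membership, module profiles, module-count/richness coupling, cross-dataset module tracking, climate-phase ratio tests |
| Assembly | abundance-weighted βMNTD, βNTI against tip-shuffle nulls (±2 ⇒ heterogeneous/homogeneous selection), abundance-adjusted Raup–Crick on Bray–Curtis (±0.95 ⇒ dispersal limitation / homogenizing dispersal), residual drift |
| Transport | row-stochastic transport matrix from 30-day drifter subtrajectories on a 0.5° grid, multi-year tracer advection, mean-velocity fields, station-window tracer concentrations |
| Synthetic data | planted Gaussian-niche modules on a latitudinal gradient, module-clustered ultrametric phylogenies, multinomial sequencing noise, drifter trajectories in a convergent velocity field |

All inputs and outputs are plain text (TSV/CSV/newick/JSON), so any stage
runs standalone.

## Worked example

The default configuration builds a toy world — 2 oceans × 8 stations ×
3 depths, 5 planted niche modules (60 ASVs), 200 drifters converging on
±30° — and runs the full chain in about 2 minutes:

```r
library(oceanmodules)
res <- run_all(default_config(), outdir = "om_run")

igraph::ecount(res$net$graph)        # 316 positive edges over 60 ASVs
res$net$assign$modularity_Q          # 0.7984 with 5 modules
res$net$null$null_p                  # 0 (none of 999 rewired nulls reach it)

map <- asv_module_map(res$synth$specs)
adjusted_rand_index(map$module_id[match(names(res$net$assign$membership),
                                        map$asv_id)],
                    res$net$assign$membership)
# 1 -- the planted partition is recovered exactly

res$loc$peak$peak_abslat             # 25.71: local modularity peaks in the
                                     #   planted 25-35 deg mixing band
res$loc$coupling                     # slope 8.94, r2 0.48, p 4.0e-08:
                                     #   more co-occurring modules, higher richness
res$trans$coupling                   # Spearman rho 0.47, p 6.9e-04: tracer
                                     #   accumulation tracks local modularity
```

Reading the numbers: the network's five clusters coincide with the five
planted niche modules (adjusted Rand index 1); per-sample modularity is
highest near |latitude| 26°, inside the band where the planted warm and
cold niches overlap and where the synthetic surface currents converge; and
stations where the 5-year drifter tracer piles up are the stations with the
most mixed (modular) communities — the package's physical-biological
coupling claim, demonstrated end to end on data whose truth is known.

Individual stages work on ordinary objects:

```r
counts <- read_counts_tsv("om_run/preprocess/filtered.tsv")
r <- sparcc(counts)                       # compositional correlations
res <- bootstrap_pvalues(counts, 999)     # + permutation significance
edges <- significant_edges(res)           # r >= 0.5, BH p <= 0.05
```

A CLI mirrors the stages:

```sh
Rscript inst/cli/oceanmodules run --config run.json --seed 1 --outdir om_run
Rscript inst/cli/oceanmodules filter --counts counts.tsv --metadata metadata.csv --out filtered.tsv
Rscript inst/cli/oceanmodules rarefy --counts filtered.tsv --depth 8000 --seed 1 --out rarefied.tsv
```
(after installation the launcher is also available at
`system.file("cli", "oceanmodules", package = "oceanmodules")`)

## Documentation

The methods vignette (`vignettes/oceanmodules-methods.Rmd`) describes the
models, the synthetic world and its deliberate simplifications, numerical
choices, and known limitations.
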