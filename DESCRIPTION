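Package: oceanmodules
Title: Co-Occurrence Modules, Assembly Mechanisms and Drifter Transport in Ocean Microbiomes
Version: 0.1.0
Authors@R: person("Ocean", "Modules Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Dissects marine prokaryotic amplicon (ASV) communities into
    co-occurrence modules and links their spatial mixing to surface-current
    transport. Provides SparCC compositional correlation inference with
    bootstrap significance, Girvan-Newman edge-betweenness module detection
    with rewiring null tests, per-sample subnetwork modularity, phylogenetic
    and compositional null models of community assembly (beta-MNTD/beta-NTI
    and abundance-weighted Raup-Crick), weighted UniFrac, and a
    drifter-derived transport-matrix tracer simulation on a lat/lon grid.
    Includes a synthetic-data generator that emulates latitudinal niche
    structure, compositional sequencing noise, module-clustered phylogenies
    and drifter trajectories, so the full pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
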