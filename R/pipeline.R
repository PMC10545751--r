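# End-to-end orchestration: one configuration drives synthetic-data
# generation, preprocessing, per-subset SparCC, global network assembly and
# clustering, per-sample structure, assembly-mechanism classification and
# the transport-matrix tracer, with a provenance manifest. All stage
# outputs are plain-text tabular files so any stage can be re-run alone.

#' Default pipeline configuration (toy scale)
#'
#' Two oceans x 8 stations x 3 depths x 1 size fraction (48 samples), 5
#' planted modules of 12 ASVs, 200 drifters for one simulated year, SparCC
#' with 999 bootstraps, 999 network rewirings, 199 assembly nulls and a
#' 5-year tracer run on a 0.5 deg grid. Completes in minutes on one CPU.
#'
#' @return nested named list of all stage parameters.
#' @export
default_config <- function() {
  list(
    seed = 1,
    synth = list(
      n_stations = 8, depths = c(20, 60, 170),
      oceans = c("atlantic", "pacific"), fractions = c("0.2-3"),
      lat_range = c(-60, 60), n_modules = 5, n_asvs_per_module = 12,
      mean_depth = 21791, n_drifters = 200, n_days = 360,
      lon_halfwidth = 25,
      convergence_latitudes = c(-30, 30), meridional_amplitude = 10,
      zonal_amplitude = 5, diffusion_sigma = 5),
    filter = list(min_total_frac = 1e-5, c1_abund = 0.01, c2_abund = 0.001,
                  c2_samples = 0.02, c3_samples = 0.05),
    rarefy = list(depth = 8000),
    sparcc = list(n_boot = 999, r_min = 0.5, alpha = 0.05,
                  exclusion_threshold = 0.1, n_exclusion_rounds = 10,
                  min_subset_samples = 5),
    network = list(n_rewire = 999, p_rewire = 0.5),
    localstruct = list(min_fraction = 0.01, loess_span = 0.5),
    assembly = list(n_null = 199),
    # the toy drifter fleet cannot populate a 0.5 deg global grid (the
    # grid_spec default for study-scale data); 2 deg keeps several
    # observations per visited cell at 200 drifters
    transport = list(dx = 2, dy = 2, dt_days = 30, n_years = 5,
                     steps_per_year = 12, n_lon_cells = 10,
                     lat_range = c(-70, 70), lon_range = c(-180, 180)))
}

#' Validate a pipeline configuration
#'
#' Checks every numeric parameter against its documented range and errors
#' before any computation starts.
#'
#' @param config nested list as from \code{\link{default_config}}.
#' @return invisibly TRUE.
#' @export
validate_config <- function(config) {
  chk <- function(ok, what) assert_that(isTRUE(ok), "invalid config: %s", what)
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed")
  s <- config$synth
  chk(s$n_stations >= 2, "synth$n_stations >= 2")
  chk(length(s$depths) >= 1 && all(s$depths > 0), "synth$depths")
  chk(s$n_modules >= 1 && s$n_asvs_per_module >= 1, "synth module counts")
  chk(s$mean_depth >= 1000, "synth$mean_depth >= 1000")
  chk(s$n_drifters >= 1 && s$n_days >= 1, "synth drifters")
  chk(s$meridional_amplitude >= 0 && s$zonal_amplitude >= 0 &&
        s$diffusion_sigma >= 0, "synth velocity field")
  chk(config$rarefy$depth >= 1, "rarefy$depth >= 1")
  sp <- config$sparcc
  chk(sp$n_boot >= 1, "sparcc$n_boot >= 1")
  chk(sp$r_min > 0 && sp$r_min <= 1, "sparcc$r_min in (0, 1]")
  chk(sp$alpha > 0 && sp$alpha <= 1, "sparcc$alpha in (0, 1]")
  chk(sp$n_exclusion_rounds >= 0, "sparcc$n_exclusion_rounds >= 0")
  nw <- config$network
  chk(nw$n_rewire >= 1, "network$n_rewire >= 1")
  chk(nw$p_rewire >= 0 && nw$p_rewire <= 1, "network$p_rewire in [0, 1]")
  chk(config$localstruct$min_fraction >= 0 && config$localstruct$min_fraction < 1,
      "localstruct$min_fraction in [0, 1)")
  chk(config$assembly$n_null >= 2, "assembly$n_null >= 2")
  tr <- config$transport
  chk(tr$dx > 0 && tr$dy > 0 && tr$dt_days > 0, "transport grid/dt")
  chk(tr$n_years >= 1 && tr$steps_per_year >= 1, "transport years")
  chk(tr$n_lon_cells >= 1, "transport$n_lon_cells >= 1")
  invisible(TRUE)
}

#' Read / write a pipeline configuration as JSON
#' @param config nested list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Loess-smoothed latitudinal profile of local modularity
#'
#' Fits loess of local Q on absolute latitude and returns the fitted curve
#' and the latitude of its maximum (the modularity "peak" used to locate the
#' community mixing zone). The curve is evaluated on the observed latitude
#' support only: with the few distinct station latitudes of a transect
#' design, loess prediction between stations is ill-conditioned, while the
#' smoothed values at the stations themselves are stable.
#'
#' @param local_q per-sample local modularity (NA allowed).
#' @param latitude per-sample latitude (signed; absolute value is used).
#' @param span loess span (default 0.5).
#' @return list(peak_abslat, abslat (distinct observed values), fitted).
#' @export
latitudinal_q_peak <- function(local_q, latitude, span = 0.5) {
  ok <- is.finite(local_q) & is.finite(latitude)
  assert_that(sum(ok) >= 10, "need >= 10 samples with defined local Q")
  al <- abs(latitude[ok])
  q <- local_q[ok]
  # loess-style tricube local-linear smoother, implemented directly:
  # stats::loess is numerically unstable when most latitudes are exact ties
  # (few stations, many samples each), which transect designs always have
  h <- span * max(diff(range(al)), 1e-6)
  grid <- sort(unique(round(al, 6)))
  pred <- vapply(grid, function(x0) {
    w <- pmax(0, 1 - (abs(al - x0) / h)^3)^3
    if (sum(w > 0) == 0) return(NA_real_)
    xc <- al - x0
    sw <- sum(w)
    vx <- sum(w * xc^2) / sw - (sum(w * xc) / sw)^2
    if (vx < 1e-8) return(sum(w * q) / sw)
    b <- (sum(w * xc * q) / sw - sum(w * xc) * sum(w * q) / sw^2) / vx
    a <- sum(w * q) / sw - b * sum(w * xc) / sw
    a  # prediction at x0 (xc = 0)
  }, 0)
  list(peak_abslat = grid[which.max(pred)], abslat = grid, fitted = pred)
}

#' Run the full pipeline from one configuration
#'
#' Executes synthetic-data generation, abundance filtering (per ocean),
#' rarefaction and diversity, SparCC per (ocean, fraction, layer) subset on
#' unrarefied filtered counts, network merge + edge-betweenness clustering +
#' rewiring null test, per-sample local structure, assembly-mechanism
#' classification on the rarefied table, and the drifter transport tracer.
#' Writes all stage outputs and a manifest (parameters, seed, md5 per file)
#' under \code{outdir}; re-running with the same config and seed reproduces
#' every file bit-identically.
#'
#' @param config nested list (see \code{\link{default_config}}).
#' @param outdir output directory.
#' @param quiet suppress progress messages (default FALSE).
#' @return invisibly, a list with the main in-memory results (counts,
#'   metadata, network, assignment, sample table, mechanism calls, tracer,
#'   correlations, manifest path).
#' @export
run_all <- function(config = default_config(), outdir = tempfile("omrun"),
                    quiet = FALSE) {
  validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_invalid("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  s <- config$synth

  say("[synthdata] generating inputs")
  synth <- stage("synthdata", {
    specs <- default_module_specs(s$n_modules, s$n_asvs_per_module)
    metadata <- generate_metadata(s$n_stations, s$depths, s$oceans,
                                  s$fractions, s$lat_range, seed = seed)
    counts <- generate_counts(specs, metadata, seed = seed,
                              mean_depth = s$mean_depth)
    tree <- generate_phylogeny(specs, seed = seed)
    field <- velocity_field_spec(s$convergence_latitudes,
                                 s$meridional_amplitude, s$zonal_amplitude,
                                 s$diffusion_sigma)
    # deploy drifters in a longitude box around each basin's stations so
    # that tracer fields and station windows overlap
    lons <- ocean_base_lons(s$oceans)
    per_basin <- ceiling(s$n_drifters / length(s$oceans))
    traj <- do.call(rbind, lapply(s$oceans, function(oc) {
      tj <- generate_trajectories(
        field, per_basin, s$n_days,
        seed = derive_seed(seed, paste0("traj:", oc)),
        lon_range = lons[[oc]] + c(-1, 1) * s$lon_halfwidth)
      tj$id <- paste0(oc, "_", tj$id)
      tj
    }))
    write_synth_bundle(file.path(outdir, "synth"), counts, metadata, tree,
                       traj, config = s)
    list(specs = specs, metadata = metadata, counts = counts, tree = tree,
         field = field, traj = traj)
  })

  say("[preprocess] filtering, rarefying, diversity")
  prep <- stage("preprocess", {
    filt <- abundance_filter(synth$counts, groups = synth$metadata$ocean,
                             min_total_frac = config$filter$min_total_frac,
                             c1_abund = config$filter$c1_abund,
                             c2_abund = config$filter$c2_abund,
                             c2_samples = config$filter$c2_samples,
                             c3_samples = config$filter$c3_samples)
    rare <- rarefy(filt, depth = config$rarefy$depth, seed = seed)
    div <- data.frame(sample_id = rownames(rare), richness = richness(rare),
                      ens = ens_inverse_simpson(rare), row.names = NULL)
    dir.create(file.path(outdir, "preprocess"), showWarnings = FALSE)
    write_counts_tsv(filt, file.path(outdir, "preprocess", "filtered.tsv"))
    write_counts_tsv(rare, file.path(outdir, "preprocess", "rarefied.tsv"))
    write.table(div, file.path(outdir, "preprocess", "diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(filt = filt, rare = rare, div = div)
  })

  say("[sparcc] per-subset correlation networks")
  edges <- stage("sparcc", {
    meta <- synth$metadata[match(rownames(prep$filt), synth$metadata$sample_id), ]
    key <- interaction(meta$ocean, meta$fraction, meta$depth_layer, drop = TRUE)
    out <- list()
    for (sub in levels(key)) {
      idx <- which(key == sub)
      if (length(idx) < config$sparcc$min_subset_samples) next
      sub_counts <- prep$filt[idx, , drop = FALSE]
      res <- bootstrap_pvalues(
        sub_counts, n_boot = config$sparcc$n_boot,
        seed = derive_seed(seed, paste0("sparcc:", sub)),
        subset_label = sub,
        exclusion_threshold = config$sparcc$exclusion_threshold,
        n_exclusion_rounds = config$sparcc$n_exclusion_rounds)
      out[[sub]] <- significant_edges(res, r_min = config$sparcc$r_min,
                                      alpha = config$sparcc$alpha)
    }
    assert_that(length(out) > 0, "no subset had enough samples for SparCC")
    dir.create(file.path(outdir, "network"), showWarnings = FALSE)
    all_edges <- do.call(rbind, out)
    write.table(all_edges, file.path(outdir, "network", "subset_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  say("[netmodules] global network, clustering, null test")
  net <- stage("netmodules", {
    g <- merge_subset_networks(edges)
    assign <- edge_betweenness_clusters(g)
    null <- rewire_null_test(g, n = config$network$n_rewire,
                             p_rewire = config$network$p_rewire,
                             seed = derive_seed(seed, "rewire"))
    write_network_tsv(g, assign,
                      file.path(outdir, "network", "global_edges.tsv"),
                      file.path(outdir, "network", "membership.tsv"))
    jsonlite::write_json(
      list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
           modularity_Q = assign$modularity_Q, n_modules = assign$n_modules,
           rewire_null_p = null$null_p),
      file.path(outdir, "network", "network_summary.json"),
      auto_unbox = TRUE, digits = NA)
    list(graph = g, assign = assign, null = null)
  })

  say("[localstruct] per-sample structure")
  loc <- stage("localstruct", {
    tab <- sample_modularity_table(prep$rare, net$graph, net$assign$membership,
                                   min_fraction = config$localstruct$min_fraction)
    meta <- synth$metadata[match(tab$sample_id, synth$metadata$sample_id), ]
    tab$latitude <- meta$latitude
    prof <- module_profiles(prep$rare, net$assign$membership)
    coup <- richness_coupling(tab$n_modules_present, tab$richness)
    peak <- latitudinal_q_peak(tab$local_Q, tab$latitude,
                               span = config$localstruct$loess_span)
    dir.create(file.path(outdir, "localstruct"), showWarnings = FALSE)
    write.table(tab, file.path(outdir, "localstruct", "sample_modularity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = rownames(prof), prof,
                           check.names = FALSE),
                file.path(outdir, "localstruct", "module_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(richness_coupling = coup,
                              q_peak_abslat = peak$peak_abslat),
                         file.path(outdir, "localstruct", "localstruct.json"),
                         auto_unbox = TRUE, digits = NA)
    # module niche summaries and phylogenetic distances between modules
    mod_cols <- setdiff(colnames(prof), "unassigned")
    niches <- module_env_preferences(prof[, mod_cols, drop = FALSE], meta)
    write.table(niches, file.path(outdir, "localstruct", "niche_preferences.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mprof <- module_mean_profiles(prep$rare, net$assign$membership)
    uni <- NULL
    if (nrow(mprof) >= 2 && all(rowSums(mprof) > 0)) {
      uni <- unifrac_matrix(mprof, synth$tree)
      write.table(data.frame(module = rownames(uni), uni, check.names = FALSE),
                  file.path(outdir, "localstruct", "module_unifrac.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(uni) >= 3) wpgma(uni)  # validated here; dendrogram is plotting-only
    }
    list(table = tab, profiles = prof, coupling = coup, peak = peak,
         niches = niches, module_unifrac = uni)
  })

  say("[assembly] mechanism classification")
  asm <- stage("assembly", {
    meta <- synth$metadata[match(rownames(prep$rare), synth$metadata$sample_id), ]
    groups <- paste(meta$ocean, meta$fraction, meta$depth_layer, sep = "/")
    calls <- assembly_classify(prep$rare, synth$tree, groups = groups,
                               n_null = config$assembly$n_null,
                               seed = derive_seed(seed, "assembly"),
                               metadata = synth$metadata)
    fr <- mechanism_fractions(calls, by = "group")
    dir.create(file.path(outdir, "assembly"), showWarnings = FALSE)
    write.table(calls, file.path(outdir, "assembly", "pair_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fr, file.path(outdir, "assembly", "mechanism_fractions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(calls = calls, fractions = fr)
  })

  say("[transport] matrix, tracer, station coupling")
  trans <- stage("transport", {
    tcfg <- config$transport
    grid <- grid_spec(tcfg$dx, tcfg$dy, tcfg$lat_range, tcfg$lon_range)
    tm <- build_transport_matrix(synth$traj, grid, dt_days = tcfg$dt_days)
    states <- advect(tm, n_years = tcfg$n_years,
                     steps_per_year = tcfg$steps_per_year)
    stations <- unique(synth$metadata[, c("ocean", "station", "latitude",
                                          "longitude")])
    final <- states[nrow(states), ]
    st_tracer <- station_tracer(final, tm, stations,
                                n_lon_cells = tcfg$n_lon_cells)
    stations$tracer <- st_tracer
    # couple per-sample local Q to its station's tracer concentration
    meta <- synth$metadata[match(loc$table$sample_id, synth$metadata$sample_id), ]
    skey <- paste(meta$ocean, meta$station)
    tr_per_sample <- stations$tracer[match(skey,
                                           paste(stations$ocean, stations$station))]
    cor_qt <- spearman_test(tr_per_sample, loc$table$local_Q)
    dir.create(file.path(outdir, "transport"), showWarnings = FALSE)
    trip <- which(tm$P > 0, arr.ind = TRUE)
    write.table(data.frame(i = rownames(tm$P)[trip[, 1]],
                           j = colnames(tm$P)[trip[, 2]], p = tm$P[trip]),
                file.path(outdir, "transport", "transition_triplets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.csv(data.frame(cell = colnames(states), t(states),
                         check.names = FALSE),
              file.path(outdir, "transport", "tracer_years.csv"),
              row.names = FALSE)
    write.table(stations, file.path(outdir, "transport", "station_tracer.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mv <- mean_velocity_field(synth$traj, grid)
    write.table(mv, file.path(outdir, "transport", "velocity_field.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(tracer_modularity_spearman = cor_qt),
                         file.path(outdir, "transport", "coupling.json"),
                         auto_unbox = TRUE, digits = NA)
    list(tm = tm, states = states, stations = stations, coupling = cor_qt)
  })

  say("[manifest] writing provenance")
  files <- sort(list.files(outdir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  md5 <- tools::md5sum(file.path(outdir, files))
  manifest <- list(package = "oceanmodules",
                   version = as.character(utils::packageVersion("oceanmodules")),
                   seed = seed, config = config,
                   files = as.list(setNames(unname(md5), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(outdir = outdir, synth = synth, prep = prep, edges = edges,
                 net = net, loc = loc, asm = asm, trans = trans,
                 manifest_path = file.path(outdir, "manifest.json")))
}
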