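# Synthetic-data generator: planted niche modules along a latitudinal
# gradient, a module-clustered ultrametric phylogeny, multinomial
# (compositional) sequencing noise, and surface-drifter trajectories in a
# prescribed convergent velocity field. All downstream stages are exercised
# on these inputs, so structure and defaults mirror the sampling design the
# analysis assumes: two ocean basins, three size fractions, two depth
# layers, stations spanning a wide latitude range.

#' Specification of one planted niche module
#'
#' A module is a set of ASVs sharing an axis-aligned Gaussian niche in
#' (absolute latitude, depth, temperature). Modules are the planted truth
#' that network clustering is later asked to recover.
#'
#' @param module_id positive integer id.
#' @param n_asvs number of ASVs in the module (>= 1).
#' @param niche_center numeric c(latitude, depth, temperature); latitude is
#'   absolute (hemisphere-symmetric niches), depth in m, temperature in deg C.
#' @param niche_breadth Gaussian kernel sd in the same units; all > 0.
#' @param mean_log_abundance log-scale abundance offset of the module
#'   (dimensionless); \code{-Inf} silences the module entirely.
#' @param phylo_cluster should the module's ASVs form a clade in the
#'   generated phylogeny (TRUE gives selection scenarios phylogenetic signal)?
#' @return an object of class \code{niched_module_spec}.
#' @export
niched_module_spec <- function(module_id, n_asvs, niche_center, niche_breadth,
                               mean_log_abundance = 0, phylo_cluster = TRUE) {
  assert_that(length(module_id) == 1 && module_id >= 1 && module_id == round(module_id),
              "module_id must be a positive integer")
  assert_that(length(n_asvs) == 1 && n_asvs >= 1 && n_asvs == round(n_asvs),
              "n_asvs must be >= 1")
  assert_that(length(niche_center) == 3 && all(is.finite(niche_center)),
              "niche_center must be numeric length 3 (lat, depth, temperature)")
  assert_that(length(niche_breadth) == 3 && all(niche_breadth > 0),
              "niche_breadth must be > 0 in every dimension")
  assert_that(length(mean_log_abundance) == 1 && !is.nan(mean_log_abundance),
              "mean_log_abundance must be a single number (possibly -Inf)")
  structure(list(module_id = as.integer(module_id), n_asvs = as.integer(n_asvs),
                 niche_center = setNames(as.numeric(niche_center),
                                         c("latitude", "depth", "temperature")),
                 niche_breadth = setNames(as.numeric(niche_breadth),
                                          c("latitude", "depth", "temperature")),
                 mean_log_abundance = as.numeric(mean_log_abundance),
                 phylo_cluster = isTRUE(phylo_cluster)),
            class = "niched_module_spec")
}

#' Default planted module set
#'
#' Five module roles at toy scale (the default pipeline configuration):
#' warm-water upper (niche center 10 deg absolute latitude, 35 m), cold
#' upper (50 deg, 35 m), a transitional upper module centered on the 30 deg
#' mixing band, and warm / cold lower-epipelagic modules (150 m). Latitude
#' breadth is 8 deg: module abundance decays below one expected read a few
#' niche widths from the center (the presence-absence turnover real
#' transects show), niche overlap concentrates in the 25-35 deg band (where
#' surface currents converge in the drifter field), and adjacent modules
#' stay statistically separable for network clustering. For
#' \code{n_modules} beyond 5 the roles are recycled with latitude centers
#' shifted by 5 deg.
#'
#' @param n_modules number of modules (default 5).
#' @param n_asvs ASVs per module (default 12).
#' @param phylo_cluster default clade structure flag applied to all modules.
#' @return list of \code{niched_module_spec}.
#' @export
default_module_specs <- function(n_modules = 5, n_asvs = 12, phylo_cluster = TRUE) {
  assert_that(n_modules >= 1, "n_modules must be >= 1")
  synth_temp <- function(lat, depth) 27.5 - 22 * (abs(lat) / 60)^1.6 - 0.035 * depth
  # depth breadth 20 m keeps lower-epipelagic ASVs at exact zero in
  # upper-layer samples (and vice versa): same-latitude modules in
  # different layers would otherwise share their latitude kernel and
  # correlate spuriously within a layer subset
  roles <- list(
    warm_upper = list(lat = 10, depth = 35, b = c(8, 20, 4)),
    cold_upper = list(lat = 50, depth = 35, b = c(8, 20, 4)),
    transition = list(lat = 30, depth = 35, b = c(8, 20, 4)),
    warm_lower = list(lat = 10, depth = 170, b = c(8, 20, 4)),
    cold_lower = list(lat = 50, depth = 170, b = c(8, 20, 4)))
  lapply(seq_len(n_modules), function(id) {
    role <- roles[[(id - 1L) %% length(roles) + 1L]]
    shift <- 5 * ((id - 1L) %/% length(roles))
    la <- role$lat + shift
    niched_module_spec(id, n_asvs,
                       c(la, role$depth, synth_temp(la, role$depth)),
                       role$b, 0, phylo_cluster)
  })
}

#' Reference longitudes of the synthetic ocean basins
#'
#' Station longitudes and drifter deployment boxes share these per-basin
#' center longitudes so that tracer fields and stations overlap spatially.
#'
#' @param oceans character vector of ocean labels.
#' @return named numeric vector of center longitudes.
#' @export
ocean_base_lons <- function(oceans) {
  setNames(seq(-150, 150, length.out = max(2, length(oceans)))[seq_along(oceans)],
           oceans)
}

#' Planted ASV-to-module truth table
#'
#' ASV identifiers are deterministic sequence-hash-style hex strings derived
#' from (module, index), so phylogeny, counts and membership generated in
#' separate calls always agree on the id space.
#'
#' @param module_specs list of \code{niched_module_spec}.
#' @return data.frame with columns \code{asv_id}, \code{module_id}.
#' @export
asv_module_map <- function(module_specs) {
  rows <- lapply(module_specs, function(sp) {
    data.frame(asv_id = hex_hash(sprintf("module%03d_asv%04d",
                                         sp$module_id, seq_len(sp$n_asvs))),
               module_id = sp$module_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  assert_that(!anyDuplicated(out$asv_id), "duplicate ASV ids in module specs")
  assert_that(!anyDuplicated(vapply(module_specs, `[[`, 1L, "module_id")),
              "duplicate module ids")
  out
}

#' Generate per-sample station metadata
#'
#' One row per (ocean, station, depth, size fraction). Latitudes are evenly
#' spaced over \code{lat_range}; temperature decreases smoothly with absolute
#' latitude and depth plus additive noise; chlorophyll has a subsurface
#' maximum whose depth defines the DCM proxy, and rows are labelled
#' \code{"upper"} (depth <= station DCM) or \code{"lower"}. Remaining
#' environmental fields (salinity, oxygen, nutrients, cell counts, generation
#' time) follow smooth latitude/depth trends with noise and exist so that
#' module niche summaries have realistic covariates to average.
#'
#' @param n_stations stations per ocean (>= 2).
#' @param depths sampled depths in m (non-empty).
#' @param oceans character vector of ocean labels.
#' @param fractions size-fraction labels.
#' @param lat_range latitude extent of the transect (default -60..60).
#' @param seed integer seed.
#' @return data.frame of per-sample metadata keyed by \code{sample_id}.
#' @export
generate_metadata <- function(n_stations, depths = c(20, 40, 60, 100, 200),
                              oceans = c("atlantic", "pacific"),
                              fractions = c("0.2-3", "3-8", ">8"),
                              lat_range = c(-60, 60), seed = 1) {
  assert_that(length(n_stations) == 1 && n_stations >= 2,
              "n_stations must be >= 2")
  assert_that(length(depths) >= 1, "depths must be non-empty")
  with_seed(derive_seed(seed, "metadata"), {
    base_lon <- ocean_base_lons(oceans)
    rows <- list()
    for (oc in oceans) {
      lats <- seq(lat_range[1], lat_range[2], length.out = n_stations)
      lons <- base_lon[[oc]] + rnorm(n_stations, 0, 2)
      # station-level DCM proxy: depth of the chlorophyll maximum
      dcm <- pmax(70, rnorm(n_stations, 80, 8))
      oni <- sample(c("neutral", "el_nino", "la_nina"), n_stations,
                    replace = TRUE, prob = c(0.6, 0.2, 0.2))
      for (st in seq_len(n_stations)) {
        la <- lats[st]
        for (dp in depths) {
          temp <- max(-1.8, 27.5 - 22 * (abs(la) / 60)^1.6 - 0.035 * dp +
                        rnorm(1, 0, 0.4))
          chl <- 0.05 + (0.25 + 0.75 * abs(la) / 60) *
            exp(-((dp - dcm[st]) / 35)^2) + abs(rnorm(1, 0, 0.02))
          for (fr in fractions) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sprintf("%s_st%02d_d%03d_f%s", oc, st, dp,
                                  gsub("[^0-9A-Za-z.]", "", fr)),
              ocean = oc, station = st, latitude = la, longitude = lons[st],
              depth = dp, fraction = fr,
              depth_layer = if (dp <= dcm[st]) "upper" else "lower",
              temperature = temp,
              salinity = 34 + 1.5 * exp(-((abs(la) - 25) / 15)^2) -
                0.002 * dp + rnorm(1, 0, 0.1),
              oxygen = 300 - 4 * temp + rnorm(1, 0, 5),
              chlorophyll = chl,
              nitrate = max(0, -2 + 0.3 * abs(la) + 0.03 * dp + rnorm(1, 0, 1)),
              silicate = max(0, -1 + 0.2 * abs(la) + 0.04 * dp + rnorm(1, 0, 1)),
              cell_count = 10^(5.8 - 0.01 * abs(la) - 0.003 * dp + rnorm(1, 0, 0.1)),
              generation_time = 2 + 0.08 * abs(la) + 0.01 * dp + rnorm(1, 0, 0.3),
              oni_phase = oni[st],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- out$sample_id
    out
  })
}

# Recursive random ultrametric newick builder. `units` is a list of
# list(str=, h=) where `str` is a leaf label or a stemless clade string and
# `h` its internal height. Returns a string with stem edge so that the unit
# hangs at total height `h_parent`.
.ultra_node <- function(units, h_parent) {
  if (length(units) == 1L) {
    u <- units[[1L]]
    return(paste0(u$str, ":", sprintf("%.12f", h_parent - u$h)))
  }
  lb <- max(vapply(units, `[[`, 0, "h"))
  h_own <- lb + runif(1, 0.3, 0.8) * (h_parent - lb)
  ord <- sample(length(units))
  cut <- sample(length(units) - 1L, 1L)
  g1 <- units[ord[seq_len(cut)]]
  g2 <- units[ord[-seq_len(cut)]]
  paste0("(", .ultra_node(g1, h_own), ",", .ultra_node(g2, h_own), "):",
         sprintf("%.12f", h_parent - h_own))
}

.ultra_clade <- function(labels, height) {
  units <- lapply(labels, function(l) list(str = l, h = 0))
  if (length(units) == 1L) return(list(str = labels[[1L]], h = 0))
  lb <- 0
  h_own <- height
  ord <- sample(length(units))
  cut <- sample(length(units) - 1L, 1L)
  g1 <- units[ord[seq_len(cut)]]
  g2 <- units[ord[-seq_len(cut)]]
  list(str = paste0("(", .ultra_node(g1, h_own), ",", .ultra_node(g2, h_own), ")"),
       h = height)
}

#' Generate a rooted ultrametric phylogeny over all module ASVs
#'
#' Modules flagged \code{phylo_cluster} become monophyletic clades (internal
#' height 0.25 on a total tree height of 1); ASVs of non-clustered modules
#' are scattered as individual leaves across the backbone, so they carry no
#' phylogenetic signal. The tree is built directly as a newick string by a
#' random bifurcating ultrametric construction, then parsed with ape.
#'
#' @param module_specs list of \code{niched_module_spec} (total ASVs >= 2).
#' @param seed integer seed.
#' @param clade_height internal height of module clades (default 0.25 of
#'   total height 1).
#' @return an \code{ape::phylo}, rooted and ultrametric, tips = ASV ids.
#' @export
generate_phylogeny <- function(module_specs, seed = 1, clade_height = 0.25) {
  map <- asv_module_map(module_specs)
  assert_that(nrow(map) >= 2, "total ASV count must be >= 2")
  with_seed(derive_seed(seed, "phylogeny"), {
    units <- list()
    for (sp in module_specs) {
      ids <- map$asv_id[map$module_id == sp$module_id]
      if (sp$phylo_cluster && length(ids) > 1) {
        units[[length(units) + 1L]] <- .ultra_clade(ids, clade_height)
      } else {
        for (id in ids) units[[length(units) + 1L]] <- list(str = id, h = 0)
      }
    }
    nwk <- if (length(units) == 1L) {
      paste0(units[[1L]]$str, ";")
    } else {
      lb <- max(vapply(units, `[[`, 0, "h"))
      h_root <- max(1, lb + 0.3)
      ord <- sample(length(units))
      cut <- sample(length(units) - 1L, 1L)
      paste0("(", .ultra_node(units[ord[seq_len(cut)]], h_root), ",",
             .ultra_node(units[ord[-seq_len(cut)]], h_root), ");")
    }
    tree <- ape::read.tree(text = nwk)
    attr(tree, "newick") <- nwk
    tree
  })
}

# Gaussian niche kernel of one module evaluated at sample environments.
.niche_kernel <- function(sp, metadata) {
  z <- ((abs(metadata$latitude) - sp$niche_center[["latitude"]]) /
          sp$niche_breadth[["latitude"]])^2 +
    ((metadata$depth - sp$niche_center[["depth"]]) /
       sp$niche_breadth[["depth"]])^2 +
    ((metadata$temperature - sp$niche_center[["temperature"]]) /
       sp$niche_breadth[["temperature"]])^2
  exp(-0.5 * z)
}

#' Generate an ASV count table with planted module structure
#'
#' The expected relative abundance of ASV a (module m) in sample s is
#' proportional to
#' \code{exp(mean_log_abundance_m + eps_a + eps_as) * K_m(s)} where K_m is
#' the module's Gaussian niche kernel at s's (|latitude|, depth, temperature)
#' and eps are lognormal ASV-level offsets (a fixed per-ASV baseline and a
#' per-(ASV, sample) fluctuation). Counts are drawn multinomially at a
#' per-sample sequencing depth which is lognormal around \code{mean_depth}
#' truncated below at \code{min_depth} (so rarefaction at 8000 stays
#' meaningful).
#'
#' @param module_specs list of \code{niched_module_spec}.
#' @param metadata data.frame from \code{generate_metadata} (needs columns
#'   latitude, depth, temperature, sample_id).
#' @param depth_per_sample optional fixed sequencing depth(s), recycled;
#'   overrides the lognormal draw. Must be > 0.
#' @param seed integer seed.
#' @param mean_depth mean sequencing depth of the lognormal (default 21791,
#'   the study-scale mean).
#' @param depth_sdlog lognormal sd on the log scale (default 0.4).
#' @param min_depth truncation floor for drawn depths (default 1000).
#' @param asv_sigma sd of the fixed per-ASV log offset (default 0.5).
#' @param sample_sigma sd of the per-(ASV, sample) log noise (default 0.3).
#' @return integer matrix samples x ASVs, dimnames = (sample_id, asv_id).
#' @export
generate_counts <- function(module_specs, metadata, depth_per_sample = NULL,
                            seed = 1, mean_depth = 21791, depth_sdlog = 0.4,
                            min_depth = 1000, asv_sigma = 0.5,
                            sample_sigma = 0.3) {
  map <- asv_module_map(module_specs)
  n_s <- nrow(metadata)
  n_a <- nrow(map)
  assert_that(n_s >= 1, "metadata must be non-empty")
  if (!is.null(depth_per_sample)) {
    assert_that(all(depth_per_sample > 0),
                "sequencing depth must be positive")
  }
  with_seed(derive_seed(seed, "counts"), {
    depths <- if (is.null(depth_per_sample)) {
      pmax(min_depth,
           round(rlnorm(n_s, log(mean_depth) - depth_sdlog^2 / 2, depth_sdlog)))
    } else {
      rep_len(round(depth_per_sample), n_s)
    }
    kern <- matrix(vapply(module_specs, .niche_kernel, numeric(n_s),
                          metadata = metadata), nrow = n_s)
    mla <- vapply(module_specs, `[[`, 0, "mean_log_abundance")
    mod_index <- match(map$module_id,
                       vapply(module_specs, `[[`, 1L, "module_id"))
    asv_offset <- rnorm(n_a, 0, asv_sigma)
    counts <- matrix(0L, n_s, n_a,
                     dimnames = list(metadata$sample_id, map$asv_id))
    for (s in seq_len(n_s)) {
      logw <- mla[mod_index] + asv_offset + rnorm(n_a, 0, sample_sigma) +
        log(kern[s, mod_index])
      w <- exp(logw - max(logw[is.finite(logw)]))
      w[!is.finite(w)] <- 0
      if (sum(w) == 0) next
      counts[s, ] <- as.integer(rmultinom(1, depths[s], w / sum(w)))
    }
    counts
  })
}

#' Specification of the synthetic surface velocity field
#'
#' A hemisphere-symmetric field whose meridional component converges on the
#' given latitudes (by construction it points toward the nearest convergence
#' latitude from both sides, emulating subtropical accumulation zones), plus
#' a uniform zonal drift and isotropic Gaussian step noise.
#'
#' @param convergence_latitudes latitudes (deg) of flow convergence
#'   (default c(-30, 30)).
#' @param meridional_amplitude peak meridional speed, cm/s (>= 0).
#' @param zonal_amplitude uniform eastward speed, cm/s (>= 0).
#' @param diffusion_sigma random-walk step sd in km per 6-h step (>= 0).
#' @return object of class \code{velocity_field_spec}.
#' @export
velocity_field_spec <- function(convergence_latitudes = c(-30, 30),
                                meridional_amplitude = 10,
                                zonal_amplitude = 5,
                                diffusion_sigma = 5) {
  assert_that(meridional_amplitude >= 0 && zonal_amplitude >= 0,
              "velocity amplitudes must be >= 0")
  assert_that(diffusion_sigma >= 0, "diffusion_sigma must be >= 0")
  assert_that(length(convergence_latitudes) >= 1,
              "need at least one convergence latitude")
  structure(list(convergence_latitudes = as.numeric(convergence_latitudes),
                 meridional_amplitude = meridional_amplitude,
                 zonal_amplitude = zonal_amplitude,
                 diffusion_sigma = diffusion_sigma),
            class = "velocity_field_spec")
}

#' Evaluate the synthetic velocity field
#'
#' @param spec a \code{velocity_field_spec}.
#' @param lat latitudes (deg).
#' @return list with components \code{u} (zonal) and \code{v} (meridional),
#'   cm/s; v points toward the nearest convergence latitude.
#' @export
field_velocity <- function(spec, lat) {
  nearest <- vapply(lat, function(la) {
    spec$convergence_latitudes[which.min(abs(spec$convergence_latitudes - la))]
  }, 0)
  list(u = rep(spec$zonal_amplitude, length(lat)),
       v = spec$meridional_amplitude * tanh((nearest - lat) / 10))
}

#' Generate drogued-drifter trajectories in the synthetic field
#'
#' Positions are integrated with forward Euler at the reporting interval on
#' a spherical-degrees approximation (zonal displacement scaled by
#' 1/cos(latitude)) with Gaussian step noise. Drifter lifetimes are normal
#' around one year (sd 120 d, floor 30 d) — the typical lifetime of a
#' drogued SVP drifter — truncated at \code{n_days}. The drogue flag is
#' always TRUE: undrogued records are out of scope.
#'
#' @param field_spec a \code{velocity_field_spec}.
#' @param n_drifters number of drifters (>= 1).
#' @param n_days simulation horizon in days (>= 1).
#' @param report_interval_h reporting/integration step in hours (default 6).
#' @param seed integer seed.
#' @param lat_range,lon_range deployment box; latitude is reflected and
#'   longitude wrapped at the domain edges.
#' @return data.frame (id, time, lat, lon, drogued); time is ISO-8601 UTC.
#' @export
generate_trajectories <- function(field_spec, n_drifters, n_days,
                                  report_interval_h = 6, seed = 1,
                                  lat_range = c(-65, 65),
                                  lon_range = c(-180, 180)) {
  assert_that(inherits(field_spec, "velocity_field_spec"),
              "field_spec must be a velocity_field_spec")
  assert_that(n_drifters >= 1, "n_drifters must be >= 1")
  assert_that(n_days >= 1, "n_days must be >= 1")
  assert_that(field_spec$diffusion_sigma >= 0, "diffusion_sigma must be >= 0")
  dt_s <- report_interval_h * 3600
  deg_per_m <- 1 / 111195
  origin <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  with_seed(derive_seed(seed, "trajectories"), {
    out <- vector("list", n_drifters)
    for (d in seq_len(n_drifters)) {
      life <- min(n_days, max(30, rnorm(1, 365, 120)))
      n_steps <- floor(life * 24 / report_interval_h)
      lat <- numeric(n_steps + 1)
      lon <- numeric(n_steps + 1)
      lat[1] <- runif(1, lat_range[1], lat_range[2])
      lon[1] <- runif(1, lon_range[1], lon_range[2])
      for (k in seq_len(n_steps)) {
        vel <- field_velocity(field_spec, lat[k])
        coslat <- max(0.2, cos(lat[k] * pi / 180))
        dlat <- vel$v * 0.01 * dt_s * deg_per_m +
          rnorm(1, 0, field_spec$diffusion_sigma) / 111.195
        dlon <- vel$u * 0.01 * dt_s * deg_per_m / coslat +
          rnorm(1, 0, field_spec$diffusion_sigma) / (111.195 * coslat)
        la <- lat[k] + dlat
        # reflect at the latitude walls of the domain
        if (la > lat_range[2]) la <- 2 * lat_range[2] - la
        if (la < lat_range[1]) la <- 2 * lat_range[1] - la
        lat[k + 1] <- la
        lo <- lon[k] + dlon
        lon[k + 1] <- ((lo + 180) %% 360) - 180
      }
      out[[d]] <- data.frame(
        id = sprintf("drifter%05d", d),
        time = format(origin + seq(0, n_steps) * dt_s, "%Y-%m-%dT%H:%M:%SZ"),
        lat = lat, lon = lon, drogued = TRUE, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

# ---- plain-text readers/writers for the generator's outputs ----

#' Write / read an ASV count table as TSV (rows = ASVs, columns = samples)
#' @param counts integer matrix samples x ASVs.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(asv_id = colnames(counts), t(counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @return \code{read_counts_tsv}: integer matrix samples x ASVs.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write generator outputs and the full generator configuration to a directory
#'
#' Emits counts TSV, metadata CSV, newick tree, trajectories CSV and a JSON
#' config documenting every generator parameter.
#'
#' @param dir output directory (created if needed).
#' @param counts,metadata,tree,trajectories generator outputs.
#' @param config named list of generator parameters to document.
#' @return invisibly, the written file paths.
#' @export
write_synth_bundle <- function(dir, counts, metadata, tree, trajectories,
                               config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             tree = file.path(dir, "tree.nwk"),
             trajectories = file.path(dir, "trajectories.csv"),
             config = file.path(dir, "synth_config.json"))
  write_counts_tsv(counts, paths[["counts"]])
  write.csv(metadata, paths[["metadata"]], row.names = FALSE)
  ape::write.tree(tree, paths[["tree"]])
  write.csv(trajectories, paths[["trajectories"]], row.names = FALSE)
  jsonlite::write_json(config, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
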