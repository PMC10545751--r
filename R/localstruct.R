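# Per-sample network structure: induced single-sample subnetworks of the
# global co-occurrence network, local modularity under the global module
# membership, module abundance profiles, module counting, richness
# coupling, cross-dataset module tracking by shared ASV identifiers, and
# the climate-phase module-ratio test.

#' Induced subnetwork of one sample
#'
#' Filters the global network's nodes to the ASVs present in the sample and
#' returns the induced subgraph (which may be empty).
#'
#' @param global_network an \code{igraph}.
#' @param sample_asvs character vector of ASV ids present in the sample.
#' @return induced \code{igraph} subgraph.
#' @export
sample_subnetwork <- function(global_network, sample_asvs) {
  keep <- intersect(igraph::V(global_network)$name, sample_asvs)
  igraph::induced_subgraph(global_network, keep)
}

#' Local modularity of a sample subnetwork under the global membership
#'
#' Q is computed on the subgraph using the restriction of the global module
#' membership. For an edgeless subgraph the quantity is undefined and
#' \code{NA} is returned (reported as missing downstream).
#'
#' @param subgraph induced subgraph from \code{\link{sample_subnetwork}}.
#' @param global_membership named vector ASV -> module id of the global
#'   clustering.
#' @return Q, or \code{NA_real_} for an edgeless subgraph.
#' @export
local_modularity <- function(subgraph, global_membership) {
  if (igraph::ecount(subgraph) == 0) return(NA_real_)
  modularity_q(subgraph, global_membership)
}

#' Per-sample module relative-abundance profiles
#'
#' Each module's fraction is the share of the sample's reads carried by that
#' module's ASVs; the remainder is the unassigned fraction (reads of ASVs
#' outside the network/module set). With \code{normalize = "assigned"}
#' module fractions are renormalized over assigned reads only (the
#' unassigned column then reports the assigned-read share of total reads
#' as \code{1 - coverage} complement is no longer meaningful, so it is 0
#' whenever any read is assigned).
#'
#' @param counts samples x ASVs matrix.
#' @param membership named vector ASV -> module id.
#' @param normalize "total" (default: fractions of all reads) or "assigned".
#' @return matrix samples x (modules..., "unassigned"); rows sum to 1.
#' @export
module_profiles <- function(counts, membership, normalize = c("total", "assigned")) {
  normalize <- match.arg(normalize)
  .check_counts(counts)
  mods <- sort(unique(membership))
  out <- matrix(0, nrow(counts), length(mods) + 1,
                dimnames = list(rownames(counts),
                                c(as.character(mods), "unassigned")))
  tot <- rowSums(counts)
  assigned_cols <- colnames(counts) %in% names(membership)
  for (i in seq_along(mods)) {
    asvs <- names(membership)[membership == mods[i]]
    cols <- colnames(counts) %in% asvs
    out[, i] <- if (any(cols)) rowSums(counts[, cols, drop = FALSE]) else 0
  }
  out[, "unassigned"] <- tot - rowSums(out[, seq_along(mods), drop = FALSE])
  if (normalize == "total") {
    out <- out / pmax(1e-300, tot)
  } else {
    assigned <- rowSums(out[, seq_along(mods), drop = FALSE])
    out[, seq_along(mods)] <- out[, seq_along(mods), drop = FALSE] /
      pmax(1e-300, assigned)
    out[, "unassigned"] <- ifelse(assigned > 0, 0, 1)
  }
  out
}

#' Number of modules present in a sample
#'
#' Counts modules whose profile fraction exceeds \code{min_fraction}
#' (strictly); the default 1% guards against counting single stray reads.
#'
#' @param profile matrix from \code{\link{module_profiles}} (or one row).
#' @param min_fraction presence threshold (default 0.01).
#' @return integer vector per sample.
#' @export
modules_present <- function(profile, min_fraction = 0.01) {
  if (is.null(dim(profile))) profile <- t(as.matrix(profile))
  mods <- setdiff(colnames(profile), "unassigned")
  as.integer(rowSums(profile[, mods, drop = FALSE] > min_fraction))
}

#' Linear coupling of richness to the number of co-occurring modules
#'
#' Ordinary least squares of richness on the per-sample module count with a
#' two-sided test on the slope.
#'
#' @param n_modules integer vector per sample.
#' @param richness numeric vector per sample.
#' @return list(slope, r2, p, n).
#' @export
richness_coupling <- function(n_modules, richness) {
  assert_that(length(n_modules) == length(richness) && length(richness) >= 3,
              "need >= 3 paired samples")
  assert_that(var(n_modules) > 0, "zero variance in module counts")
  fit <- lm(richness ~ n_modules)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]), n = length(richness))
}

#' Per-sample local network summary table
#'
#' For every sample: nodes present in the global network, local modularity
#' under the global membership, number of modules present (profile fraction
#' > \code{min_fraction}) and richness.
#'
#' @param counts samples x ASVs matrix (typically rarefied).
#' @param network global \code{igraph}.
#' @param membership named ASV -> module vector.
#' @param min_fraction module presence threshold (default 0.01).
#' @return data.frame (sample_id, n_nodes_present, local_Q,
#'   n_modules_present, richness).
#' @export
sample_modularity_table <- function(counts, network, membership,
                                    min_fraction = 0.01) {
  .check_counts(counts)
  prof <- module_profiles(counts, membership)
  nmod <- modules_present(prof, min_fraction)
  rich <- richness(counts)
  out <- data.frame(sample_id = rownames(counts),
                    n_nodes_present = NA_integer_, local_Q = NA_real_,
                    n_modules_present = nmod, richness = rich,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (s in seq_len(nrow(counts))) {
    present <- colnames(counts)[counts[s, ] > 0]
    sg <- sample_subnetwork(network, present)
    out$n_nodes_present[s] <- igraph::vcount(sg)
    out$local_Q[s] <- local_modularity(sg, membership)
  }
  out
}

#' Track modules in an external dataset sharing the ASV id scheme
#'
#' Because ASV ids are sequence hashes, module membership transfers to any
#' other table using the same scheme. Returns module profiles over the
#' external samples plus per-sample coverage (fraction of reads assigned to
#' any module).
#'
#' @param external_counts samples x ASVs matrix with hash ids.
#' @param membership named ASV -> module vector from the reference network.
#' @return list(profiles, coverage); warns when no ids overlap.
#' @export
track_modules <- function(external_counts, membership) {
  .check_counts(external_counts)
  overlap <- intersect(colnames(external_counts), names(membership))
  if (length(overlap) == 0) {
    warning("no ASV id overlap with the module membership; coverage is 0")
  }
  prof <- module_profiles(external_counts, membership)
  list(profiles = prof, coverage = 1 - prof[, "unassigned"])
}

#' Climate-phase module-ratio test
#'
#' Tests whether the (log10) abundance ratio of two modules differs between
#' two climate phases (e.g. El Nino vs other). A pseudocount equal to a
#' tenth of the smallest nonzero fraction keeps the ratio finite. Reports
#' Welch's t-test and a label-permutation test on |t|.
#'
#' @param profiles matrix from \code{\link{module_profiles}}.
#' @param phase_labels vector of phase labels per sample (exactly 2 distinct
#'   values after dropping NA; both with >= 2 samples).
#' @param module_a,module_b module column names (defaults "2" and "6").
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list(p_welch, p_perm, t, log_ratios, phases).
#' @export
phase_ratio_test <- function(profiles, phase_labels, module_a = "2",
                             module_b = "6", n_perm = 999, seed = 1) {
  assert_that(all(c(module_a, module_b) %in% colnames(profiles)),
              "modules %s/%s not found in profiles", module_a, module_b)
  ok <- !is.na(phase_labels)
  profiles <- profiles[ok, , drop = FALSE]
  phase_labels <- phase_labels[ok]
  phases <- unique(phase_labels)
  assert_that(length(phases) == 2, "need exactly two phases, got %d",
              length(phases))
  assert_that(all(table(phase_labels) >= 2), "each phase needs >= 2 samples")
  a <- profiles[, module_a]
  b <- profiles[, module_b]
  nz <- c(a[a > 0], b[b > 0])
  eps <- if (length(nz)) min(nz) / 10 else 1e-6
  lr <- log10((a + eps) / (b + eps))
  grp <- phase_labels == phases[1]
  # Welch t robust to zero within-group variance (degenerate toy inputs):
  # equal means give t = 0 / p = 1, different means t = Inf / p = 0
  welch <- function(x, y) {
    se2 <- var(x) / length(x) + var(y) / length(y)
    dm <- mean(x) - mean(y)
    if (se2 == 0) {
      return(list(t = if (dm == 0) 0 else Inf,
                  p = if (dm == 0) 1 else 0))
    }
    t_stat <- dm / sqrt(se2)
    df <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                     (var(y) / length(y))^2 / (length(y) - 1))
    list(t = t_stat, p = 2 * pt(-abs(t_stat), df))
  }
  tt <- welch(lr[grp], lr[!grp])
  t_obs <- abs(tt$t)
  perm_t <- with_seed(derive_seed(seed, "phaseperm"), {
    vapply(seq_len(n_perm), function(i) {
      g <- sample(grp)
      abs(welch(lr[g], lr[!g])$t)
    }, 0)
  })
  list(p_welch = tt$p,
       p_perm = (sum(perm_t >= t_obs) + 1) / (n_perm + 1),
       t = t_obs, log_ratios = lr, phases = phases)
}
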