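# Count-table preprocessing: the conservative abundance filter, rarefaction,
# alpha diversity, weighted UniFrac between module profiles with WPGMA
# linkage, and abundance-weighted environmental niche summaries.

.check_counts <- function(counts) {
  assert_that(is.matrix(counts) && nrow(counts) >= 1 && ncol(counts) >= 1,
              "count table must be a non-empty samples x ASVs matrix")
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "count table needs sample ids (rownames) and ASV ids (colnames)")
  assert_that(!anyDuplicated(rownames(counts)) && !anyDuplicated(colnames(counts)),
              "sample and ASV ids must be unique")
  invisible(TRUE)
}

#' Conservative abundance filter for ASV tables
#'
#' Retains an ASV iff its total relative abundance exceeds 0.001% of all
#' reads in the table AND at least one of: (1) it reaches a relative
#' abundance > 1% in some sample; (2) it is present at relative abundance
#' > 0.1% of a sample in at least 2% of samples; (3) it is present (any
#' abundance) in at least 5% of samples. Thresholds are strict inequalities
#' as printed; the sample-fraction criteria use >= on the raw fraction (no
#' ceiling), so e.g. 2% of 50 samples is exactly 1 sample. When
#' \code{groups} is given (e.g. ocean basin per sample), the filter is
#' applied within each group and an ASV is kept if it survives in any group.
#'
#' @param counts integer matrix samples x ASVs.
#' @param groups optional factor/character of length nrow(counts); filter is
#'   applied individually per group, keeping the union of survivors.
#' @param min_total_frac global threshold on total relative abundance
#'   (default 1e-5, i.e. 0.001%).
#' @param c1_abund per-sample relative abundance for criterion 1 (default 0.01).
#' @param c2_abund,c2_samples abundance and sample-fraction for criterion 2
#'   (defaults 0.001 and 0.02).
#' @param c3_samples sample-fraction for criterion 3 (default 0.05).
#' @return the filtered count matrix (same samples, surviving ASV columns).
#' @export
abundance_filter <- function(counts, groups = NULL, min_total_frac = 1e-5,
                             c1_abund = 0.01, c2_abund = 0.001,
                             c2_samples = 0.02, c3_samples = 0.05) {
  .check_counts(counts)
  assert_that(sum(counts) > 0, "count table contains no reads")
  if (!is.null(groups)) {
    assert_that(length(groups) == nrow(counts),
                "groups must have one entry per sample")
    keep <- Reduce(`|`, lapply(split(seq_len(nrow(counts)), groups), function(idx) {
      sub <- counts[idx, , drop = FALSE]
      surv <- colnames(abundance_filter(sub, NULL, min_total_frac, c1_abund,
                                        c2_abund, c2_samples, c3_samples))
      colnames(counts) %in% surv
    }))
    return(counts[, keep, drop = FALSE])
  }
  total <- sum(counts)
  rel <- counts / pmax(1, rowSums(counts))
  n_s <- nrow(counts)
  global_ok <- colSums(counts) / total > min_total_frac
  crit1 <- apply(rel, 2, max) > c1_abund
  crit2 <- colSums(rel > c2_abund) / n_s >= c2_samples
  crit3 <- colSums(counts > 0) / n_s >= c3_samples
  counts[, global_ok & (crit1 | crit2 | crit3), drop = FALSE]
}

#' Rarefy samples to equal sequencing depth
#'
#' Samples with fewer total reads than \code{depth} are dropped; the rest
#' are subsampled without replacement to exactly \code{depth} reads
#' (vegan-style). Reproducible given \code{seed}.
#'
#' @param counts integer matrix samples x ASVs.
#' @param depth target depth (default 8000).
#' @param seed integer seed.
#' @return rarefied integer matrix (possibly fewer rows).
#' @export
rarefy <- function(counts, depth = 8000, seed = 1) {
  .check_counts(counts)
  assert_that(length(depth) == 1 && depth >= 1, "depth must be >= 1")
  keep <- rowSums(counts) >= depth
  out <- counts[keep, , drop = FALSE]
  with_seed(derive_seed(seed, "rarefy"), {
    for (s in seq_len(nrow(out))) {
      x <- out[s, ]
      if (sum(x) == depth) next
      drawn <- sample.int(sum(x), depth)
      # positions 1..sum(x) laid out ASV by ASV; count how many land in each
      cum <- cumsum(x)
      out[s, ] <- tabulate(findInterval(drawn, cum + 0.5) + 1L, ncol(out))
    }
  })
  storage.mode(out) <- "integer"
  out
}

#' Per-sample richness and effective number of species (inverse Simpson)
#'
#' Richness counts ASVs with count > 0; ENS is \eqn{1 / \sum p_i^2}. Both
#' expect a rarefied table; an all-zero sample is an error (the quantities
#' are undefined).
#'
#' @param counts integer matrix samples x ASVs.
#' @return named numeric vector per sample.
#' @export
richness <- function(counts) {
  .check_counts(counts)
  assert_that(all(rowSums(counts) > 0), "all-zero sample: richness undefined")
  rowSums(counts > 0)
}

#' @rdname richness
#' @export
ens_inverse_simpson <- function(counts) {
  .check_counts(counts)
  assert_that(all(rowSums(counts) > 0), "all-zero sample: ENS undefined")
  p <- counts / rowSums(counts)
  1 / rowSums(p^2)
}

# Per-edge descendant-tip abundance mass for a profile on an ape tree.
.edge_mass <- function(tree, p) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  mass <- numeric(n_node)
  mass[seq_len(n_tip)] <- p[tree$tip.label]
  # postorder: children before parents
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    mass[eo$edge[k, 1]] <- mass[eo$edge[k, 1]] + mass[eo$edge[k, 2]]
  }
  # return mass under each edge of the original edge ordering
  mass[tree$edge[, 2]]
}

#' Normalized weighted UniFrac distance between two abundance profiles
#'
#' \deqn{d = \sum_e l_e |a_e - b_e| / \sum_e l_e (a_e + b_e)} where the sums
#' run over tree edges and a_e is the fraction of community A descending
#' from edge e. The normalization bounds the distance to [0, 1]. Profiles
#' are renormalized to sum to 1; every named taxon with positive abundance
#' must be a tip of the tree.
#'
#' @param profile_a,profile_b named non-negative vectors (names = tree tips).
#' @param tree rooted \code{ape::phylo} with branch lengths.
#' @return distance in [0, 1].
#' @export
weighted_unifrac <- function(profile_a, profile_b, tree) {
  assert_that(inherits(tree, "phylo") && !is.null(tree$edge.length),
              "tree must be a phylo with branch lengths")
  norm_profile <- function(p, who) {
    p <- p[p > 0]
    missing <- setdiff(names(p), tree$tip.label)
    assert_that(length(missing) == 0,
                "profile %s has taxa missing from the tree: %s", who,
                paste(missing, collapse = ", "))
    assert_that(sum(p) > 0, "profile %s has zero total abundance", who)
    full <- setNames(numeric(length(tree$tip.label)), tree$tip.label)
    full[names(p)] <- p / sum(p)
    full
  }
  a <- norm_profile(profile_a, "a")
  b <- norm_profile(profile_b, "b")
  am <- .edge_mass(tree, a)
  bm <- .edge_mass(tree, b)
  l <- tree$edge.length
  den <- sum(l * (am + bm))
  if (den == 0) return(0)
  sum(l * abs(am - bm)) / den
}

#' All-pairs weighted UniFrac distance matrix
#'
#' @param profiles matrix rows = communities (e.g. module mean profiles),
#'   columns = taxa.
#' @param tree rooted \code{ape::phylo}.
#' @return symmetric distance matrix.
#' @export
unifrac_matrix <- function(profiles, tree) {
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- weighted_unifrac(profiles[i, ], profiles[j, ], tree)
  }
  d
}

#' WPGMA (McQuitty) hierarchical clustering of a distance matrix
#'
#' Merges the closest pair and updates distances as the unweighted average
#' of the two children's distances (\code{hclust} method "mcquitty").
#'
#' @param dist_matrix symmetric distance matrix or \code{dist}.
#' @return an \code{hclust} dendrogram.
#' @export
wpgma <- function(dist_matrix) {
  hclust(as.dist(dist_matrix), method = "mcquitty")
}

#' Abundance-weighted environmental niche summaries per module
#'
#' For each module and environmental parameter, computes the mean of the
#' parameter over samples weighted by the module's abundance in each sample;
#' the per-parameter means are then normalized by their total over modules
#' and standardized to z-scores across modules (population sd; a zero-sd
#' parameter yields z = 0). Modules with zero total abundance are flagged
#' (\code{NA} means) and excluded from normalization and z-scoring.
#'
#' @param module_abundances matrix samples x modules (relative or absolute
#'   weights, >= 0).
#' @param metadata data.frame with one row per sample (matched by rowname or
#'   \code{sample_id}) containing the parameters.
#' @param parameters character vector of metadata columns to summarize
#'   (default: all numeric columns except coordinates and keys).
#' @return long data.frame (module, parameter, weighted_mean, normalized, z).
#' @export
module_env_preferences <- function(module_abundances, metadata,
                                   parameters = NULL) {
  assert_that(all(module_abundances >= 0), "module abundances must be >= 0")
  ids <- rownames(module_abundances)
  meta <- if (!is.null(ids) && !is.null(metadata$sample_id))
    metadata[match(ids, metadata$sample_id), , drop = FALSE] else metadata
  assert_that(nrow(meta) == nrow(module_abundances),
              "metadata rows must match module abundance rows")
  if (is.null(parameters)) {
    num <- vapply(meta, is.numeric, TRUE)
    parameters <- setdiff(names(meta)[num],
                          c("station", "latitude", "longitude"))
  }
  mods <- colnames(module_abundances)
  if (is.null(mods)) mods <- as.character(seq_len(ncol(module_abundances)))
  out <- expand.grid(module = mods, parameter = parameters,
                     stringsAsFactors = FALSE)
  out$weighted_mean <- NA_real_
  tot <- colSums(module_abundances)
  for (k in seq_len(nrow(out))) {
    m <- match(out$module[k], mods)
    if (tot[m] == 0) next
    out$weighted_mean[k] <- weighted.mean(meta[[out$parameter[k]]],
                                          module_abundances[, m])
  }
  out$normalized <- NA_real_
  out$z <- NA_real_
  for (p in parameters) {
    sel <- out$parameter == p & !is.na(out$weighted_mean)
    v <- out$weighted_mean[sel]
    nv <- if (sum(v) != 0) v / sum(v) else v
    out$normalized[sel] <- nv
    psd <- sqrt(mean((nv - mean(nv))^2))
    out$z[sel] <- if (psd > 0) (nv - mean(nv)) / psd else 0
  }
  out
}

#' Mean relative-abundance profile of each module over its ASVs
#'
#' Utility used before \code{unifrac_matrix}: converts a count table and a
#' module membership into per-module mean relative-abundance profiles over
#' all ASVs (tips).
#'
#' @param counts samples x ASVs matrix.
#' @param membership named vector ASV -> module id.
#' @return matrix modules x ASVs of mean relative abundances.
#' @export
module_mean_profiles <- function(counts, membership) {
  .check_counts(counts)
  rel <- counts / pmax(1, rowSums(counts))
  mods <- sort(unique(membership))
  out <- matrix(0, length(mods), ncol(counts),
                dimnames = list(as.character(mods), colnames(counts)))
  for (i in seq_along(mods)) {
    asvs <- intersect(names(membership)[membership == mods[i]], colnames(counts))
    if (length(asvs) == 0) next
    prof <- colMeans(rel[, , drop = FALSE])
    keepmask <- colnames(counts) %in% asvs
    out[i, keepmask] <- prof[keepmask]
  }
  out
}
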