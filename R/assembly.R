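# Null-model classification of pairwise community assembly mechanisms.
# Phylogenetic turnover (abundance-weighted beta-MNTD) is z-scored against
# tip-shuffle nulls (beta-NTI); pairs without a significant phylogenetic
# signal are classified by the abundance-adjusted Raup-Crick index on
# Bray-Curtis, and the residual class is stochastic drift.

#' Abundance-weighted beta mean nearest taxon distance
#'
#' \deqn{0.5 (\sum_{i \in A} p_i \min_{j \in B} d_{ij} +
#'            \sum_{j \in B} p_j \min_{i \in A} d_{ij})}
#' where p are within-community relative abundances and d cophenetic
#' distances. A taxon present in both communities has nearest-taxon
#' distance 0, so identical communities give 0.
#'
#' @param pa,pb named non-negative abundance vectors (normalized internally).
#' @param dmat cophenetic distance matrix with dimnames covering both
#'   communities' taxa.
#' @return non-negative distance.
#' @export
bmntd <- function(pa, pb, dmat) {
  assert_that(sum(pa) > 0 && sum(pb) > 0,
              "community with zero total abundance")
  a <- pa[pa > 0] / sum(pa)
  b <- pb[pb > 0] / sum(pb)
  missing <- setdiff(c(names(a), names(b)), rownames(dmat))
  assert_that(length(missing) == 0, "taxa missing from distance matrix: %s",
              paste(utils::head(missing, 3), collapse = ", "))
  d_ab <- dmat[names(a), names(b), drop = FALSE]
  0.5 * (sum(a * apply(d_ab, 1, min)) + sum(b * apply(d_ab, 2, min)))
}

#' Beta nearest taxon index (z-score of beta-MNTD against tip-shuffle nulls)
#'
#' The null shuffles taxon labels on the cophenetic matrix (rows and columns
#' jointly) \code{n_null} times; \eqn{z = (obs - mean_{null}) / sd_{null}}.
#' |z| > 2 indicates selection (positive: heterogeneous, negative:
#' homogeneous).
#'
#' @param pa,pb named abundance vectors.
#' @param dmat cophenetic distance matrix over the taxon pool.
#' @param n_null null shuffles (default 999, >= 2).
#' @param seed integer seed.
#' @return list(bnti, bmntd_obs, null_mean, null_sd).
#' @export
bnti <- function(pa, pb, dmat, n_null = 999, seed = 1) {
  assert_that(n_null >= 2, "n_null must be >= 2")
  obs <- bmntd(pa, pb, dmat)
  labs <- rownames(dmat)
  nulls <- with_seed(derive_seed(seed, "bnti"), {
    vapply(seq_len(n_null), function(i) {
      perm <- sample(labs)
      dn <- dmat
      dimnames(dn) <- list(perm, perm)
      bmntd(pa, pb, dn)
    }, 0)
  })
  ns <- sd(nulls)
  assert_that(ns > 0,
              "degenerate null: all shuffled beta-MNTD values identical (sd = 0)")
  list(bnti = (obs - mean(nulls)) / ns, bmntd_obs = obs,
       null_mean = mean(nulls), null_sd = ns)
}

# Bray-Curtis dissimilarity between two count/abundance vectors.
bray_curtis <- function(x, y) {
  s <- sum(x) + sum(y)
  if (s == 0) return(0)
  sum(abs(x - y)) / s
}

# One null community: preserve richness k and total abundance n; species
# drawn without replacement with probability proportional to occurrence
# frequency; each gets one individual, the remaining n - k individuals are
# placed multinomially proportional to the pool relative abundances of the
# chosen species.
.rc_null_community <- function(k, n, pool_freq, pool_relabund) {
  sp <- sample.int(length(pool_freq), k, prob = pool_freq)
  x <- numeric(length(pool_freq))
  x[sp] <- 1
  if (n > k) {
    w <- pool_relabund[sp]
    if (sum(w) == 0) w <- rep(1, k)
    x[sp] <- x[sp] + as.numeric(rmultinom(1, n - k, w))
  }
  x
}

#' Abundance-adjusted Raup-Crick index on Bray-Curtis
#'
#' Builds \code{n_null} pairs of stochastic assemblies that preserve each
#' sample's richness and total abundance (species chosen with probability
#' proportional to occurrence frequency in the regional pool, individuals
#' placed proportional to pool relative abundance), and locates the observed
#' Bray-Curtis within the null distribution:
#' \deqn{RC = 2 (\#\{BC_{null} < BC_{obs}\} + 0.5 \#ties)/n_{null} - 1,}
#' scaled to [-1, 1]. RC > 0.95 indicates dispersal limitation, RC < -0.95
#' homogenizing dispersal.
#'
#' @param xa,xb integer count vectors over the pool's species (same order as
#'   the pool vectors).
#' @param pool_freq occurrence frequency of each species across the regional
#'   dataset (number of samples containing it).
#' @param pool_relabund relative abundance of each species in the pool.
#' @param n_null null assemblies (default 999).
#' @param seed integer seed.
#' @return RC value in [-1, 1].
#' @export
rc_bray <- function(xa, xb, pool_freq, pool_relabund, n_null = 999, seed = 1) {
  ka <- sum(xa > 0); kb <- sum(xb > 0)
  pool_size <- sum(pool_freq > 0)
  assert_that(pool_size >= max(ka, kb),
              "regional pool (%d species) smaller than sample richness (%d)",
              pool_size, max(ka, kb))
  assert_that(length(xa) == length(pool_freq) &&
                length(xb) == length(pool_freq) &&
                length(pool_relabund) == length(pool_freq),
              "pool and sample vectors must align")
  obs <- bray_curtis(xa, xb)
  na <- sum(xa); nb <- sum(xb)
  nulls <- with_seed(derive_seed(seed, "rcbray"), {
    vapply(seq_len(n_null), function(i) {
      bray_curtis(.rc_null_community(ka, na, pool_freq, pool_relabund),
                  .rc_null_community(kb, nb, pool_freq, pool_relabund))
    }, 0)
  })
  2 * ((sum(nulls < obs) + 0.5 * sum(nulls == obs)) / n_null) - 1
}

#' Classify the assembly mechanism of one sample pair
#'
#' Decision rule: beta-NTI > +2 -> heterogeneous selection; < -2 ->
#' homogeneous selection; otherwise RC_bray > 0.95 -> dispersal limitation;
#' < -0.95 -> homogenizing dispersal; else stochastic drift.
#'
#' @param bnti beta-NTI z-score.
#' @param rc RC_bray value; required (non-NA) when |bnti| <= 2.
#' @return one of "heterogeneous_selection", "homogeneous_selection",
#'   "dispersal_limitation", "homogenizing_dispersal", "drift".
#' @export
classify_mechanism <- function(bnti, rc = NA_real_) {
  assert_that(is.finite(bnti), "bnti must be a finite number")
  if (bnti > 2) return("heterogeneous_selection")
  if (bnti < -2) return("homogeneous_selection")
  assert_that(!is.na(rc), "RC_bray required when |beta-NTI| <= 2")
  if (rc > 0.95) return("dispersal_limitation")
  if (rc < -0.95) return("homogenizing_dispersal")
  "drift"
}

#' Pairwise assembly-mechanism calls for a count table
#'
#' Runs beta-NTI for every sample pair (within \code{groups} when given,
#' mirroring the within-(ocean, fraction, layer) design), computes RC_bray
#' only where the phylogenetic signal is not significant, and classifies.
#' Per-pair seeds are derived from (seed, pair index) so results do not
#' depend on evaluation order. The regional pool for RC_bray is the full
#' table (occurrence frequencies and summed relative abundances).
#'
#' @param counts samples x ASVs matrix (counts or relative abundances times
#'   a common depth; RC nulls use integer totals, so rarefied counts are the
#'   natural input).
#' @param tree rooted \code{ape::phylo} over (at least) the table's ASVs.
#' @param groups optional per-sample grouping; pairs are formed within
#'   groups only.
#' @param n_null nulls for both beta-NTI and RC (default 999).
#' @param seed integer seed.
#' @param metadata optional data.frame (matched by sample id) whose
#'   \code{temperature} feeds the delta-T of each pair.
#' @return data.frame (sample_a, sample_b, group, bmntd_obs, bnti, rc_bray,
#'   label, delta_t).
#' @export
assembly_classify <- function(counts, tree, groups = NULL, n_null = 999,
                              seed = 1, metadata = NULL) {
  .check_counts(counts)
  missing_tips <- setdiff(colnames(counts), tree$tip.label)
  assert_that(length(missing_tips) == 0, "ASVs missing from tree: %s",
              paste(utils::head(missing_tips, 3), collapse = ", "))
  dmat <- ape::cophenetic.phylo(tree)[colnames(counts), colnames(counts)]
  pool_freq <- colSums(counts > 0)
  rel <- counts / rowSums(counts)
  pool_relabund <- colSums(rel) / nrow(rel)
  if (is.null(groups)) groups <- rep("all", nrow(counts))
  temp <- if (!is.null(metadata)) {
    metadata$temperature[match(rownames(counts), metadata$sample_id)]
  } else rep(NA_real_, nrow(counts))
  rows <- list()
  pair_index <- 0L
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    for (ii in seq_len(length(idx) - 1)) for (jj in seq(ii + 1, length(idx))) {
      pair_index <- pair_index + 1L
      a <- idx[ii]; b <- idx[jj]
      pseed <- derive_seed(seed, paste0("pair", pair_index))
      # pairs with identical taxon membership have beta-MNTD 0 under every
      # tip shuffle (degenerate null); no phylogenetic signal is detectable,
      # so such pairs fall through to the compositional (RC) route
      bz <- tryCatch(bnti(counts[a, ], counts[b, ], dmat, n_null, seed = pseed),
                     error = function(e) {
                       if (grepl("degenerate null", conditionMessage(e)))
                         list(bnti = NA_real_, bmntd_obs = NA_real_)
                       else stop(e)
                     })
      rc <- NA_real_
      if (is.na(bz$bnti) || abs(bz$bnti) <= 2) {
        rc <- rc_bray(counts[a, ], counts[b, ], pool_freq, pool_relabund,
                      n_null, seed = pseed)
      }
      rows[[pair_index]] <- data.frame(
        sample_a = rownames(counts)[a], sample_b = rownames(counts)[b],
        group = g, bmntd_obs = bz$bmntd_obs, bnti = bz$bnti, rc_bray = rc,
        label = classify_mechanism(ifelse(is.na(bz$bnti), 0, bz$bnti), rc),
        delta_t = abs(temp[a] - temp[b]), stringsAsFactors = FALSE)
    }
  }
  assert_that(length(rows) > 0, "no sample pairs to classify")
  do.call(rbind, rows)
}

.mechanism_levels <- c("heterogeneous_selection", "homogeneous_selection",
                       "dispersal_limitation", "homogenizing_dispersal",
                       "drift")

#' Aggregate mechanism calls into per-group label fractions
#'
#' Groups either by the call's categorical \code{group} column (or any
#' supplied vector) or, with \code{by = "deltaT"}, by binned pairwise
#' temperature difference.
#'
#' @param calls data.frame from \code{\link{assembly_classify}}.
#' @param by "group" (default) or "deltaT".
#' @param binwidth delta-T bin width in deg C (default 2).
#' @return data.frame: one row per group, one column per mechanism label
#'   (fractions summing to 1) plus \code{n_pairs}.
#' @export
mechanism_fractions <- function(calls, by = c("group", "deltaT"), binwidth = 2) {
  by <- match.arg(by)
  key <- if (by == "group") {
    as.character(calls$group)
  } else {
    assert_that(all(is.finite(calls$delta_t)),
                "delta_t missing; supply metadata with temperature")
    sprintf("[%g,%g)", floor(calls$delta_t / binwidth) * binwidth,
            (floor(calls$delta_t / binwidth) + 1) * binwidth)
  }
  out <- lapply(split(calls$label, key), function(labs) {
    tab <- table(factor(labs, levels = .mechanism_levels))
    c(as.list(as.numeric(tab) / length(labs)), n_pairs = length(labs))
  })
  df <- do.call(rbind, lapply(names(out), function(k) {
    data.frame(group = k, as.data.frame(setNames(out[[k]],
                                                 c(.mechanism_levels, "n_pairs"))),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}
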