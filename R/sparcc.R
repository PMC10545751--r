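# SparCC: compositional correlation inference from count data via the
# log-ratio variance basis approximation, with iterative exclusion of
# strongly correlated pairs, bootstrap p-values by within-ASV shuffling, and
# selection of significant positive edges.

#' Estimate component fractions from counts
#'
#' Mode \code{"pseudocount"} is deterministic: (x + 1) / sum(x + 1) per
#' sample. Mode \code{"dirichlet"} returns the mean of \code{n_draws}
#' posterior draws from Dirichlet(x + 1) per sample and converges to the
#' pseudocount fractions as \code{n_draws} grows.
#'
#' @param counts samples x ASVs matrix of non-negative counts.
#' @param mode "pseudocount" (default) or "dirichlet".
#' @param n_draws posterior draws per sample for dirichlet mode.
#' @param seed integer seed (dirichlet mode only).
#' @return matrix samples x ASVs of fractions; rows sum to 1.
#' @export
estimate_fractions <- function(counts, mode = c("pseudocount", "dirichlet"),
                               n_draws = 100, seed = 1) {
  mode <- match.arg(mode)
  assert_that(all(counts >= 0), "counts must be non-negative")
  x <- counts + 1
  if (mode == "pseudocount") {
    return(x / rowSums(x))
  }
  with_seed(derive_seed(seed, "dirichlet"), {
    out <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(counts))
    for (s in seq_len(nrow(x))) {
      g <- matrix(rgamma(n_draws * ncol(x), shape = rep(x[s, ], each = n_draws)),
                  nrow = n_draws)
      out[s, ] <- colMeans(g / rowSums(g))
    }
    out
  })
}

# Variation matrix: t_ij = var(log(f_i / f_j)) across samples, computed from
# the covariance of the per-sample log fractions.
variation_matrix <- function(fractions) {
  lg <- log(fractions)
  cv <- cov(lg)
  v <- diag(cv)
  outer(v, v, `+`) - 2 * cv
}

#' Solve the SparCC basis-variance linear system
#'
#' For p components the approximation sets M w = t with t_i the row sums of
#' the variation matrix, diag(M) = p - 1 and off-diagonal 1. For p = 3 this
#' system is exactly determined (w_1 = (t_12 + t_13 - t_23)/2, etc.), which
#' serves as a closed-form check of the solver.
#'
#' @param tmat p x p variation matrix of log-ratio variances.
#' @return numeric vector of p basis variances (clamped below at 1e-12).
#' @export
sparcc_basis_variances <- function(tmat) {
  p <- ncol(tmat)
  assert_that(p >= 3, "basis approximation needs >= 3 components")
  m <- matrix(1, p, p)
  diag(m) <- p - 1
  w <- solve(m, rowSums(tmat))
  pmax(w, 1e-12)
}

# One basis solve with an exclusion set: excluded pairs are removed from the
# linear system (their t_ij no longer contribute to the row sums and the
# corresponding off-diagonal/diagonal entries are decremented).
.sparcc_solve <- function(tmat, excluded) {
  p <- ncol(tmat)
  m <- matrix(1, p, p)
  diag(m) <- p - 1
  t_i <- rowSums(tmat)
  if (nrow(excluded) > 0) {
    for (k in seq_len(nrow(excluded))) {
      i <- excluded[k, 1]; j <- excluded[k, 2]
      m[i, j] <- m[j, i] <- m[i, j] - 1
      m[i, i] <- m[i, i] - 1
      m[j, j] <- m[j, j] - 1
      t_i[i] <- t_i[i] - tmat[i, j]
      t_i[j] <- t_i[j] - tmat[i, j]
    }
  }
  w <- tryCatch(solve(m, t_i), error = function(e) rep(mean(t_i) / p, p))
  w <- pmax(w, 1e-12)
  r <- (outer(w, w, `+`) - tmat) / (2 * sqrt(outer(w, w)))
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' SparCC correlations from a fraction matrix
#'
#' Computes the log-ratio variation matrix, solves the basis-variance
#' approximation, and iteratively excludes the most strongly correlated pair
#' (|r| above \code{exclusion_threshold}) from the system for up to
#' \code{n_exclusion_rounds} rounds, as in the original procedure. With
#' \code{n_exclusion_rounds = 0} this is the pure basis approximation. Ties
#' for the maximum |r| break lexicographically for determinism.
#'
#' @param fractions samples x ASVs fraction matrix (rows sum to 1).
#' @param exclusion_threshold exclude pairs with |r| above this (default 0.1).
#' @param n_exclusion_rounds maximum exclusion iterations (default 10).
#' @return symmetric correlation matrix in [-1, 1] with unit diagonal.
#' @export
sparcc_correlations <- function(fractions, exclusion_threshold = 0.1,
                                n_exclusion_rounds = 10) {
  p <- ncol(fractions)
  assert_that(p >= 4, paste("SparCC's basis approximation is degenerate for",
                            "fewer than 4 ASVs; compute log-ratio variances directly"))
  tmat <- variation_matrix(fractions)
  excluded <- matrix(integer(0), 0, 2)
  excl_count <- integer(p)
  r <- .sparcc_solve(tmat, excluded)
  if (n_exclusion_rounds > 0) {
    for (round in seq_len(n_exclusion_rounds)) {
      ra <- abs(r)
      ra[lower.tri(ra, diag = TRUE)] <- -Inf
      if (nrow(excluded) > 0) ra[excluded] <- -Inf
      best <- which(ra == max(ra), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, , drop = FALSE]
      if (ra[best] <= exclusion_threshold) break
      i <- best[1, 1]; j <- best[1, 2]
      # never fully exclude a component from the system
      if (excl_count[i] >= p - 2 || excl_count[j] >= p - 2) break
      excluded <- rbind(excluded, c(i, j))
      excl_count[i] <- excl_count[i] + 1L
      excl_count[j] <- excl_count[j] + 1L
      r <- .sparcc_solve(tmat, excluded)
    }
  }
  dimnames(r) <- list(colnames(fractions), colnames(fractions))
  r
}

#' SparCC on a count table
#'
#' Convenience wrapper: estimates fractions then correlations. In dirichlet
#' mode the correlation matrix is the element-wise median over
#' \code{n_inner_iter} fraction resamplings; pseudocount mode is
#' deterministic and ignores \code{n_inner_iter}.
#'
#' @param counts samples x ASVs count matrix.
#' @param mode fraction estimation mode, see \code{\link{estimate_fractions}}.
#' @param n_inner_iter Dirichlet resampling iterations (default 20).
#' @param exclusion_threshold,n_exclusion_rounds see
#'   \code{\link{sparcc_correlations}}.
#' @param seed integer seed (dirichlet mode only).
#' @return symmetric correlation matrix.
#' @export
sparcc <- function(counts, mode = c("pseudocount", "dirichlet"),
                   n_inner_iter = 20, exclusion_threshold = 0.1,
                   n_exclusion_rounds = 10, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "pseudocount") {
    fr <- estimate_fractions(counts, "pseudocount")
    return(sparcc_correlations(fr, exclusion_threshold, n_exclusion_rounds))
  }
  rs <- lapply(seq_len(n_inner_iter), function(it) {
    fr <- estimate_fractions(counts, "dirichlet", n_draws = 1,
                             seed = derive_seed(seed, paste0("inner", it)))
    sparcc_correlations(fr, exclusion_threshold, n_exclusion_rounds)
  })
  r <- apply(simplify2array(rs), c(1, 2), stats::median)
  dimnames(r) <- list(colnames(counts), colnames(counts))
  r
}

#' Bootstrap p-values for SparCC correlations
#'
#' Shuffles each ASV's counts independently across samples (destroying
#' co-variation while preserving marginals), recomputes the correlation
#' matrix \code{n_boot} times, and sets p_ij to the plain proportion of
#' bootstrap |r| at least as extreme as the observed |r| (two-sided; no
#' add-one correction, so the minimum attainable p is 0). Benjamini-Hochberg
#' adjustment is applied over the upper triangle.
#'
#' @param counts samples x ASVs count matrix.
#' @param n_boot number of shuffles (default 999).
#' @param seed integer seed.
#' @param subset_label optional (ocean, fraction, layer) label carried along.
#' @param adjust p.adjust method for the upper triangle (default "BH").
#' @param ... passed to \code{\link{sparcc}}.
#' @return object of class \code{sparcc_result}: list(r, p_raw, p_adj,
#'   subset_label, n_boot).
#' @export
bootstrap_pvalues <- function(counts, n_boot = 999, seed = 1,
                              subset_label = NULL, adjust = "BH", ...) {
  assert_that(n_boot >= 1, "n_boot must be >= 1")
  # canonical row order: makes the permutation draws (and hence p-values)
  # exactly invariant to the input's sample ordering
  if (!is.null(rownames(counts))) {
    counts <- counts[order(rownames(counts)), , drop = FALSE]
  }
  r_obs <- sparcc(counts, seed = derive_seed(seed, "obs"), ...)
  hits <- matrix(0, ncol(counts), ncol(counts))
  n <- nrow(counts)
  with_seed(derive_seed(seed, "boot"), {
    for (b in seq_len(n_boot)) {
      shuf <- apply(counts, 2, function(col) col[sample.int(n)])
      rownames(shuf) <- rownames(counts)
      r_b <- sparcc(shuf, seed = derive_seed(seed, paste0("bootinner", b)), ...)
      hits <- hits + (abs(r_b) >= abs(r_obs))
    }
  })
  p_raw <- hits / n_boot
  diag(p_raw) <- 0
  ut <- upper.tri(p_raw)
  p_adj <- p_raw
  p_adj[ut] <- p.adjust(p_raw[ut], method = adjust)
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  dimnames(p_raw) <- dimnames(p_adj) <- dimnames(r_obs)
  structure(list(r = r_obs, p_raw = p_raw, p_adj = p_adj,
                 subset_label = subset_label, n_boot = n_boot),
            class = "sparcc_result")
}

#' @export
print.sparcc_result <- function(x, ...) {
  cat(sprintf("SparCC result: %d ASVs, %d bootstraps%s\n", ncol(x$r), x$n_boot,
              if (!is.null(x$subset_label))
                paste0(", subset ", paste(x$subset_label, collapse = "/")) else ""))
  invisible(x)
}

#' Select significant positive edges from a SparCC result
#'
#' Keeps pairs with r >= \code{r_min} (inclusive) and adjusted p <=
#' \code{alpha}. Negative associations are excluded by construction: module
#' detection targets clusters of co-occurring organisms.
#'
#' @param result a \code{sparcc_result}.
#' @param r_min minimum correlation, in (0, 1] (default 0.5).
#' @param alpha maximum adjusted p (default 0.05).
#' @return data.frame (asv_i, asv_j, r, p_raw, p_adj, subset).
#' @export
significant_edges <- function(result, r_min = 0.5, alpha = 0.05) {
  assert_that(inherits(result, "sparcc_result"), "need a sparcc_result")
  assert_that(r_min > 0 && r_min <= 1, "r_min must be in (0, 1]")
  r <- result$r
  idx <- which(upper.tri(r) & r >= r_min & result$p_adj <= alpha, arr.ind = TRUE)
  subset_str <- if (is.null(result$subset_label)) NA_character_ else
    paste(result$subset_label, collapse = "/")
  data.frame(asv_i = colnames(r)[idx[, 1]], asv_j = colnames(r)[idx[, 2]],
             r = r[idx], p_raw = result$p_raw[idx], p_adj = result$p_adj[idx],
             subset = subset_str, stringsAsFactors = FALSE)
}
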