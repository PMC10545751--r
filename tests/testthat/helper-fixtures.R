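# Shared fixtures and independent oracles, all built in code.

# Two 3-cliques joined by one bridge (c-d). Hand values: m = 7,
# two-clique partition has L_c = 3, d_c = 7 per clique,
# Q = 2 * (3/7 - (7/14)^2) = 5/14.
bridge_edge_list <- function(r = 0.9, subset = "s1") {
  data.frame(asv_i = c("a", "a", "b", "d", "d", "e", "c"),
             asv_j = c("b", "c", "c", "e", "f", "f", "d"),
             r = r, subset = subset, stringsAsFactors = FALSE)
}

bridge_graph <- function() merge_subset_networks(list(bridge_edge_list()))

bridge_membership <- function() {
  setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "d", "e", "f"))
}

# Balanced 4-leaf ultrametric tree with unit branch lengths.
balanced_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# A random count table (samples x ASVs) with a realistic abundance skew.
random_count_table <- function(n_samples, n_asvs, seed, depth_mean = 5000) {
  with_seed(seed, {
    base <- rlnorm(n_asvs, 0, 2)
    m <- t(vapply(seq_len(n_samples), function(s) {
      as.integer(rmultinom(1, max(100, round(rlnorm(1, log(depth_mean), 0.3))),
                           base * rlnorm(n_asvs, 0, 0.5)))
    }, integer(n_asvs)))
    dimnames(m) <- list(sprintf("s%03d", seq_len(n_samples)),
                        sprintf("asv%04d", seq_len(n_asvs)))
    m
  })
}

# Brute-force reimplementation of the three-criterion abundance filter,
# written independently of abundance_filter(): per-ASV loops, no shared
# code path.
filter_oracle <- function(counts) {
  total_reads <- sum(counts)
  keep <- logical(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    asv_total <- 0
    n_over_1pct <- 0
    n_over_01pct <- 0
    n_present <- 0
    for (i in seq_len(nrow(counts))) {
      x <- counts[i, j]
      asv_total <- asv_total + x
      rel <- x / sum(counts[i, ])
      if (rel > 0.01) n_over_1pct <- n_over_1pct + 1
      if (rel > 0.001) n_over_01pct <- n_over_01pct + 1
      if (x > 0) n_present <- n_present + 1
    }
    global <- asv_total / total_reads > 1e-5
    c1 <- n_over_1pct >= 1
    c2 <- n_over_01pct / nrow(counts) >= 0.02
    c3 <- n_present / nrow(counts) >= 0.05
    keep[j] <- global && (c1 || c2 || c3)
  }
  colnames(counts)[keep]
}

# Independent beta-MNTD oracle: plain double loop over present taxa.
bmntd_oracle <- function(pa, pb, dmat) {
  a <- pa[pa > 0] / sum(pa[pa > 0])
  b <- pb[pb > 0] / sum(pb[pb > 0])
  term_a <- 0
  for (i in names(a)) {
    term_a <- term_a + a[[i]] * min(vapply(names(b), function(j) dmat[i, j], 0))
  }
  term_b <- 0
  for (j in names(b)) {
    term_b <- term_b + b[[j]] * min(vapply(names(a), function(i) dmat[i, j], 0))
  }
  0.5 * (term_a + term_b)
}

# Edge-by-edge weighted UniFrac oracle for the balanced 4-leaf tree:
# enumerates all 6 edges explicitly.
unifrac_oracle_balanced <- function(pa, pb) {
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  # edges: A, B, C, D tip edges (length 1), two internal edges (length 1)
  masses <- function(p) c(p[["A"]], p[["B"]], p[["C"]], p[["D"]],
                          p[["A"]] + p[["B"]], p[["C"]] + p[["D"]])
  ma <- masses(pa); mb <- masses(pb)
  sum(abs(ma - mb)) / sum(ma + mb)
}
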