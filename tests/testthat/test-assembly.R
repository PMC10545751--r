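test_that("beta-MNTD matches hand values and the brute-force oracle", {
  tree <- balanced_tree()
  d <- ape::cophenetic.phylo(tree)
  # identical communities: nearest taxon is itself
  pa <- c(A = 0.7, B = 0.3)
  expect_equal(bmntd(pa, pa, d), 0)
  # disjoint single-taxon communities: half-sum of the two cophenetic
  # distances, here d(A,C) = 4 both ways -> 4
  expect_equal(bmntd(c(A = 1), c(C = 1), d), 0.5 * (d["A", "C"] + d["C", "A"]))
  # random 10-taxon pairs vs oracle
  with_seed(3, {
    labs <- paste0("t", 1:10)
    dr <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
    dimnames(dr) <- list(labs, labs)
    for (k in 1:10) {
      pa <- setNames(rexp(10) * rbinom(10, 1, 0.6), labs)
      pb <- setNames(rexp(10) * rbinom(10, 1, 0.6), labs)
      if (sum(pa) == 0 || sum(pb) == 0) next
      expect_equal(bmntd(pa, pb, dr), unname(bmntd_oracle(pa, pb, dr)),
                   tolerance = 1e-12)
    }
  })
  expect_error(bmntd(c(A = 0), c(C = 1), d), "zero total")
  expect_error(bmntd(c(A = 1, Q = 1), c(C = 1), d), "missing")
})

test_that("beta-NTI z-scores behave under null and planted structure", {
  tree <- balanced_tree()
  d <- ape::cophenetic.phylo(tree)
  # observed equal to null mean -> z = 0 is impossible to construct exactly
  # here, but z must be finite and reproducible
  z1 <- bnti(c(A = 1, B = 1), c(C = 1, D = 1), d, n_null = 99, seed = 5)
  z2 <- bnti(c(A = 1, B = 1), c(C = 1, D = 1), d, n_null = 99, seed = 5)
  expect_identical(z1, z2)
  expect_error(bnti(c(A = 1), c(B = 1), d, n_null = 1), "n_null")
  # degenerate null: communities spanning all taxa
  expect_error(bnti(setNames(rep(1, 4), rownames(d)),
                    setNames(rep(1, 4), rownames(d)), d, n_null = 19),
               "degenerate")
})

test_that("Raup-Crick index is bounded, reproducible, and matches enumeration", {
  freq <- c(3, 2, 1)
  rel <- c(0.5, 0.3, 0.2)
  xa <- c(3L, 2L, 0L); xb <- c(0L, 2L, 3L)
  rc <- rc_bray(xa, xb, freq, rel, n_null = 199, seed = 2)
  expect_true(rc >= -1 && rc <= 1)
  expect_identical(rc, rc_bray(xa, xb, freq, rel, n_null = 199, seed = 2))
  # identical communities sit at the bottom of the null distribution (a
  # pool rich enough that exact null ties are rare)
  freq10 <- 10:1
  rel10 <- (10:1) / 55
  x10 <- c(12L, 9L, 7L, 5L, 3L, 0L, 0L, 0L, 0L, 0L)
  expect_lt(rc_bray(x10, x10, freq10, rel10, n_null = 199, seed = 3), -0.9)
  expect_error(rc_bray(c(1L, 1L, 1L), xb, c(2, 1, 0), rel), "pool")

  # tiny-pool enumeration oracle: pool of 3 species, richness 2, 2 reads
  # per community. every null community is a pair of species with one read
  # each; enumerate all 9 (pair_a, pair_b) combinations exactly.
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  pair_prob <- function(p) {
    # sequential sampling without replacement, prob proportional to freq
    w <- freq / sum(freq)
    w[p[1]] * (freq[p[2]] / (sum(freq) - freq[p[1]])) +
      w[p[2]] * (freq[p[1]] / (sum(freq) - freq[p[2]]))
  }
  probs <- vapply(pairs, pair_prob, 0)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  vec <- function(p) {
    x <- numeric(3)
    x[p] <- 1
    x
  }
  xa2 <- c(1L, 1L, 0L); xb2 <- c(1L, 0L, 1L)
  obs <- sum(abs(xa2 - xb2)) / sum(xa2 + xb2)
  p_less <- p_tie <- 0
  for (i in 1:3) for (j in 1:3) {
    bc <- sum(abs(vec(pairs[[i]]) - vec(pairs[[j]]))) /
      sum(vec(pairs[[i]]) + vec(pairs[[j]]))
    pr <- probs[i] * probs[j]
    if (bc < obs) p_less <- p_less + pr
    if (bc == obs) p_tie <- p_tie + pr
  }
  rc_exact <- 2 * (p_less + 0.5 * p_tie) - 1
  rc_mc <- rc_bray(xa2, xb2, freq, rel, n_null = 1999, seed = 7)
  # Monte-Carlo estimate of the exactly enumerated value
  expect_equal(rc_mc, rc_exact, tolerance = 0.06)
})

test_that("the five-way decision rule is applied verbatim", {
  expect_equal(classify_mechanism(2.5), "heterogeneous_selection")
  expect_equal(classify_mechanism(-2.5), "homogeneous_selection")
  expect_equal(classify_mechanism(0.3, 0.1), "drift")
  expect_equal(classify_mechanism(1.0, 0.97), "dispersal_limitation")
  expect_equal(classify_mechanism(-1.0, -0.97), "homogenizing_dispersal")
  # boundaries: |bnti| = 2 and |rc| = 0.95 are NOT selection/dispersal
  expect_equal(classify_mechanism(2, 0.95), "drift")
  expect_equal(classify_mechanism(-2, -0.95), "drift")
  expect_error(classify_mechanism(0.5), "RC_bray required")
  expect_error(classify_mechanism(NaN, 0), "finite")
})

test_that("mechanism fractions close to 1 per group and bin by delta-T", {
  calls <- data.frame(
    group = c("g1", "g1", "g1", "g2"),
    label = c("drift", "drift", "heterogeneous_selection", "drift"),
    delta_t = c(0.5, 2.5, 2.7, 5.1))
  fr <- mechanism_fractions(calls)
  expect_equal(fr$drift[fr$group == "g1"], 2 / 3)
  expect_equal(rowSums(fr[, 2:6]), rep(1, 2), ignore_attr = TRUE)
  frt <- mechanism_fractions(calls, by = "deltaT", binwidth = 2)
  expect_setequal(frt$group, c("[0,2)", "[2,4)", "[4,6)"))
  expect_equal(frt$n_pairs[frt$group == "[2,4)"], 2)
})

test_that("classifier pipeline is deterministic and order-invariant", {
  specs <- default_module_specs(2, 6)
  md <- generate_metadata(3, c(20, 170), "a", "f", seed = 2)
  counts <- generate_counts(specs, md, depth_per_sample = 2000, seed = 2)
  tree <- generate_phylogeny(specs, seed = 2)
  counts <- counts[, colSums(counts) > 0]
  calls1 <- assembly_classify(counts, tree, n_null = 49, seed = 9)
  calls2 <- assembly_classify(counts, tree, n_null = 49, seed = 9)
  expect_identical(calls1, calls2)
  expect_true(all(calls1$label %in% c(
    "heterogeneous_selection", "homogeneous_selection",
    "dispersal_limitation", "homogenizing_dispersal", "drift")))
  expect_true(all(is.na(calls1$rc_bray) | abs(calls1$rc_bray) <= 1))
})
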