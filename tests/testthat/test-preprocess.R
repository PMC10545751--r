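test_that("abundance filter applies the three printed criteria", {
  # 20 samples; ASV totals 0.005% of reads, present in 2 samples (10% >= 5%)
  counts <- matrix(0L, 20, 2,
                   dimnames = list(sprintf("s%02d", 1:20), c("keep3", "filler")))
  counts[, "filler"] <- 10000L
  counts[c(3, 11), "keep3"] <- c(5L, 5L)  # 10/199990 = 0.005% of reads
  filt <- abundance_filter(counts)
  expect_true("keep3" %in% colnames(filt))

  # fails the global 0.001% threshold despite 3% in one sample
  counts <- matrix(0L, 20, 2,
                   dimnames = list(sprintf("s%02d", 1:20), c("rare", "filler")))
  counts[, "filler"] <- 100000L
  counts[1, "rare"] <- 9L   # 9/2000009 = 0.00045% < 0.001%, but 9/100009 samplewise
  # make it 3% of its own sample but tiny globally: shrink that sample
  counts[1, "filler"] <- 300L
  expect_lt(sum(counts[, "rare"]) / sum(counts), 1e-5)
  expect_gt(counts[1, "rare"] / sum(counts[1, ]), 0.01)
  expect_false("rare" %in% colnames(abundance_filter(counts)))
  expect_error(abundance_filter(matrix(integer(0), 0, 0)), "non-empty")
})

test_that("abundance filter matches the brute-force oracle on random tables", {
  for (s in 1:5) {
    counts <- random_count_table(50, 200, seed = s)
    expect_identical(colnames(abundance_filter(counts)), filter_oracle(counts))
  }
})

test_that("filter is idempotent, a subset, and respects basin grouping", {
  counts <- random_count_table(40, 150, seed = 99)
  filt <- abundance_filter(counts)
  expect_true(all(colnames(filt) %in% colnames(counts)))
  expect_identical(abundance_filter(filt), filt)
  # per-basin application keeps the union of survivors
  groups <- rep(c("A", "B"), each = 20)
  by_basin <- abundance_filter(counts, groups = groups)
  survA <- filter_oracle(counts[1:20, ])
  survB <- filter_oracle(counts[21:40, ])
  expect_setequal(colnames(by_basin), union(survA, survB))
})

test_that("rarefaction drops shallow samples and subsamples exactly", {
  counts <- rbind(shallow = c(4000L, 3999L), deep = c(9000L, 1000L),
                  exact = c(4000L, 4000L))
  colnames(counts) <- c("x", "y")
  r <- rarefy(counts, depth = 8000, seed = 1)
  expect_false("shallow" %in% rownames(r))   # 7999 < 8000
  expect_equal(unname(rowSums(r)), c(8000, 8000))
  expect_identical(r["exact", ], counts["exact", ])  # already at depth
  expect_true(all(r["deep", ] <= counts["deep", ]))
  # reproducible under the same seed
  expect_identical(rarefy(counts, 8000, seed = 3), rarefy(counts, 8000, seed = 3))
  expect_error(rarefy(counts, depth = 0), "depth")
})

test_that("richness and inverse-Simpson ENS follow the definitions", {
  counts <- rbind(even = c(4000L, 4000L), skew = c(7999L, 1L),
                  mono = c(8000L, 0L))
  colnames(counts) <- c("x", "y")
  expect_equal(unname(richness(counts)), c(2, 2, 1))
  ens <- ens_inverse_simpson(counts)
  expect_equal(unname(ens[["even"]]), 2)
  expect_equal(unname(ens[["skew"]]), 1 / ((7999 / 8000)^2 + (1 / 8000)^2))
  expect_equal(unname(ens[["mono"]]), 1)
  # agrees with vegan and never exceeds richness
  tab <- random_count_table(15, 40, seed = 4)
  expect_equal(unname(ens_inverse_simpson(tab)),
               unname(vegan::diversity(tab, "invsimpson")), tolerance = 1e-12)
  expect_true(all(ens_inverse_simpson(tab) <= richness(tab) + 1e-9))
  zero <- matrix(0L, 1, 2, dimnames = list("z", c("x", "y")))
  expect_error(richness(zero), "all-zero")
})

test_that("weighted UniFrac matches the edge-by-edge oracle and is a pseudometric", {
  tree <- balanced_tree()
  expect_equal(weighted_unifrac(c(A = .5, B = .5), c(A = .5, B = .5), tree), 0)
  # disjoint sister pairs: hand value 1
  pa <- c(A = .5, B = .5); pb <- c(C = .5, D = .5)
  expect_equal(weighted_unifrac(pa, pb, tree), unifrac_oracle_balanced(
    c(A = .5, B = .5, C = 0, D = 0), c(A = 0, B = 0, C = .5, D = .5)))
  # random profiles vs oracle, plus symmetry and triangle inequality
  with_seed(8, {
    for (k in 1:10) {
      p <- matrix(rexp(12), 3, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
      d12 <- weighted_unifrac(p[1, ], p[2, ], tree)
      expect_equal(d12, unifrac_oracle_balanced(p[1, ], p[2, ]), tolerance = 1e-12)
      expect_equal(d12, weighted_unifrac(p[2, ], p[1, ], tree))
      d13 <- weighted_unifrac(p[1, ], p[3, ], tree)
      d23 <- weighted_unifrac(p[2, ], p[3, ], tree)
      expect_lte(d12, d13 + d23 + 1e-12)
      expect_true(d12 >= 0 && d12 <= 1)
    }
  })
  expect_error(weighted_unifrac(c(A = 1, Z = 1), c(A = 1), tree), "Z")
})

test_that("WPGMA merges by unweighted average linkage", {
  d <- matrix(c(0, 1, 3, 1, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- wpgma(d)
  expect_equal(hc$height, c(1, 3))
  expect_equal(hc$method, "mcquitty")
})

test_that("module environmental preferences are weighted, normalized, z-scored", {
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   temperature = c(10, 10, 25), salinity = c(34, 35, 36))
  ab <- matrix(c(1, 2, 0,   0, 0, 3,   1, 1, 1), 3, 3,
               dimnames = list(md$sample_id, c("m1", "m2", "m3")))
  pref <- module_env_preferences(ab, md, parameters = c("temperature", "salinity"))
  # m1 present only where T = 10
  expect_equal(pref$weighted_mean[pref$module == "m1" &
                                    pref$parameter == "temperature"], 10)
  # z-scores use the population sd: means (1,2,3) -> (-1.2247, 0, 1.2247)
  # after total-sum normalization z is unchanged (affine invariance)
  means <- c(1, 2, 3)
  zs <- (means - mean(means)) / sqrt(mean((means - mean(means))^2))
  expect_equal(unname(zs), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  for (p in c("temperature", "salinity")) {
    z <- pref$z[pref$parameter == p]
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  }
  # equal weighted means give zero z for all
  md2 <- data.frame(sample_id = c("s1", "s2"), temperature = c(12, 12))
  ab2 <- matrix(c(1, 1, 2, 0), 2, 2,
                dimnames = list(md2$sample_id, c("m1", "m2")))
  pref2 <- module_env_preferences(ab2, md2, parameters = "temperature")
  expect_equal(pref2$z, c(0, 0))
  # zero-abundance module flagged as NA and excluded
  ab3 <- cbind(ab2, m3 = c(0, 0))
  pref3 <- module_env_preferences(ab3, md2, parameters = "temperature")
  expect_true(is.na(pref3$weighted_mean[pref3$module == "m3"]))
  expect_equal(sum(!is.na(pref3$z)), 2)
})
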