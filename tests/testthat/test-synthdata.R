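test_that("generate_metadata produces the full factorial design with sane gradients", {
  md <- generate_metadata(2, depths = 20, oceans = "a", fractions = "f", seed = 1)
  expect_equal(nrow(md), 2)

  md <- generate_metadata(34, depths = c(20, 40, 60, 100, 150, 200),
                          oceans = c("atlantic", "pacific"),
                          fractions = c("0.2-3", "3-8", ">8"), seed = 7)
  expect_equal(nrow(md), 34 * 6 * 2 * 3)
  # temperature decreases with |latitude| at fixed depth
  at20 <- md[md$depth == 20 & md$fraction == "0.2-3" & md$ocean == "atlantic", ]
  expect_lt(cor(abs(at20$latitude), at20$temperature, method = "spearman"), 0)
  # deepest samples are always below the DCM proxy
  expect_true(all(md$depth_layer[md$depth == 200] == "lower"))
  expect_error(generate_metadata(0, depths = 20), "n_stations")
})

test_that("generate_phylogeny is ultrametric and clusters flagged modules", {
  one <- list(niched_module_spec(1, 2, c(10, 30, 25), c(10, 50, 5)))
  tr <- generate_phylogeny(one, seed = 1)
  expect_equal(length(tr$tip.label), 2)
  depths <- diag(ape::vcv(tr))
  expect_equal(unname(diff(range(depths))), 0, tolerance = 1e-9)

  specs <- lapply(1:3, function(k)
    niched_module_spec(k, 5, c(10 * k, 30, 20), c(10, 50, 5)))
  tr <- generate_phylogeny(specs, seed = 2)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  co <- ape::cophenetic.phylo(tr)
  map <- asv_module_map(specs)
  same <- outer(map$module_id, map$module_id, `==`)
  co <- co[map$asv_id, map$asv_id]
  off <- upper.tri(co)
  expect_lt(mean(co[off & same]), mean(co[off & !same]))

  # without clades: permutation test finds no within/between difference
  specs0 <- lapply(specs, function(sp) {
    sp$phylo_cluster <- FALSE
    sp
  })
  tr0 <- generate_phylogeny(specs0, seed = 3)
  co0 <- ape::cophenetic.phylo(tr0)[map$asv_id, map$asv_id]
  obs <- mean(co0[off & !same]) - mean(co0[off & same])
  perms <- with_seed(11, vapply(1:999, function(i) {
    pm <- sample(nrow(co0))
    cp <- co0[pm, pm]
    mean(cp[off & !same]) - mean(cp[off & same])
  }, 0))
  p <- mean(perms >= obs)
  expect_gt(p, 0.05)
})

test_that("generate_counts plants multinomial niche structure", {
  warm <- niched_module_spec(1, 5, c(0, 20, 27), c(12, 50, 6))
  cold <- niched_module_spec(2, 5, c(55, 20, 7), c(12, 50, 6))
  md <- data.frame(sample_id = c("eq", "polar"), latitude = c(0, 55),
                   depth = 20, temperature = c(27, 7))
  one_sample <- md[1, , drop = FALSE]
  cnt <- generate_counts(list(warm), one_sample, depth_per_sample = 1000, seed = 1)
  expect_equal(unname(rowSums(cnt)), 1000)
  expect_true(all(cnt >= 0) && is.integer(cnt))

  # planted design in expectation over 20 seeds
  map <- asv_module_map(list(warm, cold))
  rel_warm_eq <- rel_warm_po <- rel_cold_eq <- rel_cold_po <- numeric(20)
  for (s in 1:20) {
    cnt <- generate_counts(list(warm, cold), md, depth_per_sample = 5000, seed = s)
    rel <- cnt / rowSums(cnt)
    wa <- map$asv_id[map$module_id == 1]
    co <- map$asv_id[map$module_id == 2]
    rel_warm_eq[s] <- sum(rel["eq", wa]); rel_warm_po[s] <- sum(rel["polar", wa])
    rel_cold_eq[s] <- sum(rel["eq", co]); rel_cold_po[s] <- sum(rel["polar", co])
  }
  expect_gt(mean(rel_warm_eq), mean(rel_warm_po))
  expect_gt(mean(rel_cold_po), mean(rel_cold_eq))

  # -Inf log abundance silences a module entirely
  mute <- niched_module_spec(3, 4, c(0, 20, 27), c(12, 50, 6),
                             mean_log_abundance = -Inf)
  cnt <- generate_counts(list(warm, mute), one_sample,
                         depth_per_sample = 2000, seed = 5)
  map2 <- asv_module_map(list(warm, mute))
  expect_true(all(cnt[, map2$asv_id[map2$module_id == 3]] == 0))
  expect_error(generate_counts(list(warm), one_sample,
                               depth_per_sample = 0, seed = 1), "depth")
})

test_that("generate_trajectories advects toward convergence latitudes", {
  still <- velocity_field_spec(meridional_amplitude = 0, zonal_amplitude = 0,
                               diffusion_sigma = 0)
  tj <- generate_trajectories(still, 3, 10, seed = 1)
  for (d in split(tj, tj$id)) {
    expect_equal(var(d$lat), 0)
    expect_equal(var(d$lon), 0)
  }
  expect_true(all(tj$drogued))

  # fix cadence: 30 days at 6 h = 121 positions
  tj <- generate_trajectories(still, 5, 30, seed = 2)
  expect_true(all(table(tj$id) == 121))

  # drifters starting at 10N drift north toward the 30N convergence
  conv <- velocity_field_spec(convergence_latitudes = 30,
                              meridional_amplitude = 15, zonal_amplitude = 0,
                              diffusion_sigma = 2)
  drift <- vapply(1:50, function(s) {
    tj <- with_seed(s, {
      # place one drifter deterministically at 10N by overriding deployment
      t1 <- generate_trajectories(conv, 1, 60, seed = s)
      t1
    })
    first <- tj$lat[1]
    (tj$lat[nrow(tj)] - first) * sign(30 - first)
  }, 0)
  expect_gt(mean(drift), 0)
  expect_error(velocity_field_spec(diffusion_sigma = -1), "diffusion_sigma")
})

test_that("synthetic outputs are bit-identical under a fixed seed", {
  specs <- default_module_specs(3, 4)
  md1 <- generate_metadata(4, c(20, 100), "a", "f", seed = 42)
  md2 <- generate_metadata(4, c(20, 100), "a", "f", seed = 42)
  expect_identical(md1, md2)
  expect_identical(generate_counts(specs, md1, seed = 42),
                   generate_counts(specs, md2, seed = 42))
  expect_identical(ape::write.tree(generate_phylogeny(specs, seed = 42)),
                   ape::write.tree(generate_phylogeny(specs, seed = 42)))
  fs <- velocity_field_spec()
  expect_identical(generate_trajectories(fs, 3, 20, seed = 42),
                   generate_trajectories(fs, 3, 20, seed = 42))
})
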