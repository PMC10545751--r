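# Build a small trajectory table by hand: positions every 6 h.
make_traj <- function(id, lat, lon, drogued = TRUE) {
  n <- length(lat)
  data.frame(id = id,
             time = format(as.POSIXct("2020-01-01", tz = "UTC") +
                             (seq_len(n) - 1) * 21600, "%Y-%m-%dT%H:%M:%SZ"),
             lat = lat, lon = lon, drogued = drogued,
             stringsAsFactors = FALSE)
}

test_that("transport matrix counts subtrajectories and row-normalizes", {
  grid <- grid_spec(1, 1, c(-5, 5), c(-5, 5))
  # stationary drifter over 61 days -> identity on its cell
  tj <- make_traj("d1", rep(0.5, 245), rep(0.5, 245))
  tm <- build_transport_matrix(tj, grid)
  expect_equal(unname(tm$P), matrix(1, 1, 1))

  # toy: every subtrajectory cell1 -> cell2, then cell2 -> cell2
  # 30 d = 120 steps; drifter sits in cell1 for the first window, jumps to
  # cell2 and stays: transitions (1->2), (2->2), ...
  lat <- c(rep(0.5, 120), rep(1.5, 245))
  tj <- make_traj("d2", lat, rep(0.5, length(lat)))
  tm <- build_transport_matrix(tj, grid)
  expect_equal(dim(tm$P), c(2, 2))
  # rows ordered by cell id; cell of lat 0.5 comes first
  expect_equal(unname(tm$P), rbind(c(0, 1), c(0, 1)))

  # mass conservation and row-stochasticity on synthetic trajectories
  fs <- velocity_field_spec()
  tj <- generate_trajectories(fs, 30, 90, seed = 4)
  g2 <- grid_spec(2, 2)
  tm2 <- build_transport_matrix(tj, g2)
  expect_equal(unname(rowSums(tm2$P)), rep(1, nrow(tm2$P)), tolerance = 1e-12)
  expect_true(all(tm2$P >= 0))
  expect_error(build_transport_matrix(make_traj("d3", rep(0, 5), rep(0, 5)),
                                      grid), "too short")
})

test_that("advection conserves mass and absorbs in the toy chain", {
  grid <- grid_spec(1, 1, c(-5, 5), c(-5, 5))
  lat <- c(rep(0.5, 120), rep(1.5, 245))
  tm <- build_transport_matrix(make_traj("d", lat, rep(0.5, length(lat))), grid)
  states <- advect(tm, n_years = 2)
  # after one 30-day step everything is absorbed in cell 2; by hand,
  # P %*% P = P for this absorbing chain
  expect_equal(unname(states["year1", ]), c(0, 1))
  expect_equal(unname(states["year2", ]), c(0, 1))
  expect_equal(unname(tm$P %*% tm$P), unname(tm$P))
  # identity matrix: state constant
  tmi <- tm
  tmi$P <- diag(2)
  dimnames(tmi$P) <- dimnames(tm$P)
  si <- advect(tmi, initial = c(0.3, 0.7), n_years = 3)
  expect_equal(unname(si["year3", ]), c(0.3, 0.7))
  # mass conserved at every emitted state over 60 steps
  fs <- velocity_field_spec()
  tj <- generate_trajectories(fs, 40, 120, seed = 6)
  tm2 <- build_transport_matrix(tj, grid_spec(2, 2))
  st <- advect(tm2, n_years = 5, steps_per_year = 12)
  expect_equal(unname(rowSums(st)), rep(1, 6), tolerance = 1e-9)
  expect_error(advect(tm, initial = c(-1, 1), n_years = 1), "non-negative")
})

test_that("mean velocity field recovers prescribed speeds", {
  grid <- grid_spec(2, 2)
  # stationary drifter: 0 cm/s
  st <- make_traj("d1", rep(0.5, 10), rep(0.5, 10))
  mv <- mean_velocity_field(st, grid)
  expect_equal(mv$speed_cms, rep(0, nrow(mv)))
  # 1 deg latitude (111.195 km) in 24 h = 128.7 cm/s
  tj <- make_traj("d2", seq(0, 1, length.out = 5), rep(0, 5))
  mv <- mean_velocity_field(tj, grid)
  expect_equal(mv$speed_cms, rep(111195 * 100 / 86400, nrow(mv)),
               tolerance = 1e-3)
  # cell means rank-correlate with the prescribed field speed
  fs <- velocity_field_spec(meridional_amplitude = 12, zonal_amplitude = 3,
                            diffusion_sigma = 0)
  tj <- generate_trajectories(fs, 150, 60, seed = 9)
  mv <- mean_velocity_field(tj, grid)
  vel <- field_velocity(fs, mv$lat)
  prescribed <- sqrt(vel$u^2 + vel$v^2)
  expect_gte(cor(mv$speed_cms, prescribed, method = "spearman"), 0.8)
})

test_that("station tracer averages a longitudinal window with edge clipping", {
  grid <- grid_spec(1, 1, c(-5, 5), c(-10, 10))
  cells <- grid_cell(grid, rep(0.5, 20), seq(-9.5, 9.5, 1))
  state <- setNames(rep(2, 20), as.character(cells))
  tm <- list(grid = grid)
  class(tm) <- "transport_matrix"
  stations <- data.frame(station = "s1", latitude = 0.5, longitude = 0.5)
  # uniform tracer: value equals the uniform value
  expect_equal(station_tracer(state, tm, stations), 2)
  # single-cell spike at the station: spike / window
  spike <- setNames(rep(0, 20), as.character(cells))
  spike[as.character(grid_cell(grid, 0.5, 0.5))] <- 10
  expect_equal(station_tracer(spike, tm, stations), 1)
  # window clipped at the grid edge: explicit loop oracle
  st_edge <- data.frame(station = "s2", latitude = 0.5, longitude = -9.5)
  got <- station_tracer(spike, tm, st_edge)
  ix <- floor((-9.5 - grid$lon_range[1]) / grid$dx)
  window <- (ix + (-4:5))
  window <- window[window >= 0 & window < grid$nx]
  iy <- floor((0.5 - grid$lat_range[1]) / grid$dy)
  vals <- spike[as.character(iy * grid$nx + window + 1)]
  vals[is.na(vals)] <- 0
  expect_equal(got, mean(vals))
  expect_error(station_tracer(state, tm,
                              data.frame(station = "far", latitude = 50,
                                         longitude = 0)), "far")
})

test_that("convergent flow accumulates tracer at +-30 monotonically", {
  fs <- velocity_field_spec(meridional_amplitude = 12, zonal_amplitude = 4,
                            diffusion_sigma = 4)
  tj <- generate_trajectories(fs, 120, 360, seed = 10, lon_range = c(-40, 10))
  grid <- grid_spec(2, 2)
  tm <- build_transport_matrix(tj, grid)
  st <- advect(tm, n_years = 5)
  conv <- abs(abs(tm$cells$lat) - 30) <= 4
  mass_at_conv <- rowSums(st[, conv, drop = FALSE])
  expect_true(all(diff(mass_at_conv) > 0))
  # column mass concentrates near the convergence cells by year 5
  expect_gt(mass_at_conv[["year5"]], 2 * mass_at_conv[["year0"]])
  # a non-divergent flow (doubly stochastic transition matrix: here a
  # cyclic shift, i.e. uniform zonal drift with periodic wrap) keeps an
  # initially uniform tracer exactly uniform: max/min ratio stays at 1
  k <- 12
  perm <- diag(k)[c(2:k, 1), ]
  dimnames(perm) <- list(as.character(1:k), as.character(1:k))
  tm0 <- structure(list(P = perm,
                        cells = data.frame(cell = 1:k, lat = 0,
                                           lon = seq(-11, 11, by = 2)),
                        dt_days = 30, grid = grid),
                   class = "transport_matrix")
  st0 <- advect(tm0, n_years = 5)
  final <- st0["year5", ]
  expect_lt(max(final) / min(final), 1.5)
})
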