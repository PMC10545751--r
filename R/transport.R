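# Drifter transport matrix: grid the ocean into dx x dy cells, subdivide
# trajectories into non-overlapping dt-day subtrajectories, count cell-to-
# cell transitions and row-normalize into a Markov transition matrix; advect
# a virtual tracer to locate accumulation zones; compute mean drifter speed
# per cell; and average tracer over a longitudinal window at station sites.

#' Lat/lon grid specification
#'
#' @param dx,dy cell size in degrees longitude / latitude (default 0.5).
#' @param lat_range,lon_range ordered grid bounds.
#' @return object of class \code{grid_spec}.
#' @export
grid_spec <- function(dx = 0.5, dy = 0.5, lat_range = c(-70, 70),
                      lon_range = c(-180, 180)) {
  assert_that(dx > 0 && dy > 0, "dx and dy must be > 0")
  assert_that(lat_range[1] < lat_range[2] && lon_range[1] < lon_range[2],
              "grid bounds must be ordered")
  structure(list(dx = dx, dy = dy, lat_range = lat_range,
                 lon_range = lon_range,
                 nx = ceiling(diff(lon_range) / dx),
                 ny = ceiling(diff(lat_range) / dy)),
            class = "grid_spec")
}

#' Cell index of positions on a grid
#'
#' 1-based, row-major over latitude rows; \code{NA} outside the bounds.
#'
#' @param grid a \code{grid_spec}.
#' @param lat,lon coordinates in degrees.
#' @return integer-valued cell ids.
#' @export
grid_cell <- function(grid, lat, lon) {
  ix <- floor((lon - grid$lon_range[1]) / grid$dx)
  iy <- floor((lat - grid$lat_range[1]) / grid$dy)
  ok <- ix >= 0 & ix < grid$nx & iy >= 0 & iy < grid$ny
  out <- iy * grid$nx + ix + 1
  out[!ok] <- NA
  out
}

#' @rdname grid_cell
#' @param cell integer cell ids.
#' @return \code{grid_cell_center}: list(lat, lon) of cell centers.
#' @export
grid_cell_center <- function(grid, cell) {
  ix <- (cell - 1) %% grid$nx
  iy <- (cell - 1) %/% grid$nx
  list(lat = grid$lat_range[1] + (iy + 0.5) * grid$dy,
       lon = grid$lon_range[1] + (ix + 0.5) * grid$dx)
}

.check_trajectories <- function(trajectories) {
  need <- c("id", "time", "lat", "lon", "drogued")
  assert_that(all(need %in% names(trajectories)),
              "trajectories need columns: %s", paste(need, collapse = ", "))
}

#' Build the drifter transport matrix
#'
#' Trajectories are subdivided into non-overlapping consecutive
#' subtrajectories of length \code{dt_days}; the initial and final cell of
#' each subtrajectory are counted into N_ij and rows are normalized to sum
#' to 1, giving the probability that a tracer moves from cell i to cell j in
#' dt. The state space is restricted to visited cells; cells observed only
#' as endpoints get a self-absorbing row (P_ii = 1). Fixes are assumed
#' regular (6-hourly by default); irregular spacing is an error.
#'
#' @param trajectories data.frame (id, time, lat, lon, drogued), time-sorted
#'   within drifter.
#' @param grid a \code{grid_spec}.
#' @param dt_days subtrajectory length in days (default 30).
#' @param drogued_only drop undrogued fixes (default TRUE).
#' @return object of class \code{transport_matrix}: list(P (row-stochastic
#'   matrix over visited cells, dimnames = cell ids), cells (data.frame
#'   cell, lat, lon), dt_days, grid).
#' @export
build_transport_matrix <- function(trajectories, grid, dt_days = 30,
                                   drogued_only = TRUE) {
  .check_trajectories(trajectories)
  if (drogued_only) trajectories <- trajectories[trajectories$drogued, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (d in split(trajectories, trajectories$id)) {
    tt <- as.POSIXct(d$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    ord <- order(tt)
    d <- d[ord, , drop = FALSE]; tt <- tt[ord]
    if (length(tt) < 2) next
    step_s <- as.numeric(difftime(tt[2], tt[1], units = "secs"))
    assert_that(all(abs(diff(as.numeric(tt)) - step_s) < 1),
                "irregular fix interval for drifter %s", d$id[1])
    stride <- round(dt_days * 86400 / step_s)
    if (stride < 1 || nrow(d) <= stride) next
    starts <- seq(1, nrow(d) - stride, by = stride)
    cs <- grid_cell(grid, d$lat[starts], d$lon[starts])
    ce <- grid_cell(grid, d$lat[starts + stride], d$lon[starts + stride])
    ok <- !is.na(cs) & !is.na(ce)
    from <- c(from, cs[ok]); to <- c(to, ce[ok])
  }
  assert_that(length(from) > 0,
              "no subtrajectory of length dt could be formed (trajectories too short)")
  cells <- sort(unique(c(from, to)))
  k <- length(cells)
  p <- matrix(0, k, k, dimnames = list(as.character(cells), as.character(cells)))
  fi <- match(from, cells); ti <- match(to, cells)
  for (n in seq_along(fi)) p[fi[n], ti[n]] <- p[fi[n], ti[n]] + 1
  rs <- rowSums(p)
  for (i in seq_len(k)) {
    if (rs[i] > 0) p[i, ] <- p[i, ] / rs[i] else p[i, i] <- 1
  }
  ctr <- grid_cell_center(grid, cells)
  structure(list(P = p,
                 cells = data.frame(cell = cells, lat = ctr$lat, lon = ctr$lon),
                 dt_days = dt_days, grid = grid),
            class = "transport_matrix")
}

#' @export
print.transport_matrix <- function(x, ...) {
  cat(sprintf("Transport matrix: %d visited cells, dt = %g d, grid %gx%g deg\n",
              nrow(x$P), x$dt_days, x$grid$dx, x$grid$dy))
  invisible(x)
}

#' Advect a tracer with the transport matrix
#'
#' Applies \code{v <- v P} per dt step. A simulated year is
#' \code{steps_per_year} steps (default 12 x 30 d = 360 d). States are
#' emitted at year 0 (initial) and each year boundary. The default initial
#' condition is a uniform unit mass over the visited cells.
#'
#' @param tm a \code{transport_matrix}.
#' @param initial optional non-negative initial mass per cell (default
#'   uniform, total mass 1).
#' @param n_years number of simulated years (>= 1).
#' @param steps_per_year dt steps per year (default 12).
#' @return matrix (n_years + 1) x cells; rownames "year0".."yearN".
#' @export
advect <- function(tm, initial = NULL, n_years = 1, steps_per_year = 12) {
  assert_that(inherits(tm, "transport_matrix"), "need a transport_matrix")
  assert_that(n_years >= 1, "n_years must be >= 1")
  k <- nrow(tm$P)
  if (is.null(initial)) initial <- rep(1 / k, k)
  assert_that(length(initial) == k && all(is.finite(initial)),
              "initial mass must be finite with one value per cell")
  assert_that(all(initial >= 0), "initial mass must be non-negative")
  out <- matrix(0, n_years + 1, k,
                dimnames = list(paste0("year", 0:n_years), colnames(tm$P)))
  v <- as.numeric(initial)
  out[1, ] <- v
  for (y in seq_len(n_years)) {
    for (s in seq_len(steps_per_year)) v <- as.numeric(v %*% tm$P)
    out[y + 1, ] <- v
  }
  out
}

# Haversine great-circle distance in meters.
haversine_m <- function(lat1, lon1, lat2, lon2) {
  r <- 6371000
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180; dl <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Mean drifter speed per grid cell
#'
#' For every consecutive pair of fixes, computes great-circle displacement
#' over elapsed time and averages the speeds by the segment's starting cell.
#'
#' @param trajectories data.frame (id, time, lat, lon, drogued).
#' @param grid a \code{grid_spec}.
#' @param drogued_only drop undrogued fixes (default TRUE).
#' @return data.frame (cell, lat, lon, speed_cms, n_segments).
#' @export
mean_velocity_field <- function(trajectories, grid, drogued_only = TRUE) {
  .check_trajectories(trajectories)
  if (drogued_only) trajectories <- trajectories[trajectories$drogued, , drop = FALSE]
  cell <- numeric(0); speed <- numeric(0)
  for (d in split(trajectories, trajectories$id)) {
    tt <- as.POSIXct(d$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    ord <- order(tt)
    d <- d[ord, , drop = FALSE]; tt <- tt[ord]
    if (nrow(d) < 2) next
    n <- nrow(d)
    dist_m <- haversine_m(d$lat[-n], d$lon[-n], d$lat[-1], d$lon[-1])
    dt_s <- as.numeric(difftime(tt[-1], tt[-n], units = "secs"))
    cs <- grid_cell(grid, d$lat[-n], d$lon[-n])
    ok <- !is.na(cs) & dt_s > 0
    cell <- c(cell, cs[ok])
    speed <- c(speed, 100 * dist_m[ok] / dt_s[ok])
  }
  agg_mean <- tapply(speed, cell, mean)
  agg_n <- tapply(speed, cell, length)
  cells <- as.numeric(names(agg_mean))
  ctr <- grid_cell_center(grid, cells)
  data.frame(cell = cells, lat = ctr$lat, lon = ctr$lon,
             speed_cms = as.numeric(agg_mean), n_segments = as.integer(agg_n),
             row.names = NULL)
}

#' Tracer concentration at station locations
#'
#' Averages the tracer over a longitudinal window of \code{n_lon_cells}
#' cells centered on each station's cell (at the station's latitude row) to
#' avoid undersampling bias. Cells in the window that lie inside the grid
#' but were never visited contribute 0; cells beyond the grid edge are
#' dropped from the average. Stations outside the grid bounds are an error.
#'
#' @param state tracer vector named by cell id (one row of
#'   \code{\link{advect}}'s output).
#' @param tm the \code{transport_matrix} (for grid geometry).
#' @param stations data.frame with columns \code{latitude}, \code{longitude}
#'   and optionally \code{station} (used in error messages).
#' @param n_lon_cells window width in cells (default 10, i.e. 5 deg at 0.5).
#' @return numeric vector, one concentration per station row.
#' @export
station_tracer <- function(state, tm, stations, n_lon_cells = 10) {
  grid <- tm$grid
  out <- numeric(nrow(stations))
  offs <- seq_len(n_lon_cells) - 1 - floor((n_lon_cells - 1) / 2)
  for (s in seq_len(nrow(stations))) {
    la <- stations$latitude[s]; lo <- stations$longitude[s]
    cc <- grid_cell(grid, la, lo)
    if (is.na(cc)) {
      nm <- if (!is.null(stations$station)) stations$station[s] else s
      stop_invalid("station %s (%.2f, %.2f) outside grid bounds", nm, la, lo)
    }
    ix <- (cc - 1) %% grid$nx
    iy <- (cc - 1) %/% grid$nx
    window_ix <- ix + offs
    window_ix <- window_ix[window_ix >= 0 & window_ix < grid$nx]
    cells <- iy * grid$nx + window_ix + 1
    conc <- state[as.character(cells)]
    conc[is.na(conc)] <- 0
    out[s] <- mean(conc)
  }
  out
}
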