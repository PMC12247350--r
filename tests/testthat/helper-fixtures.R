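# Fixture builders and independent oracles used across the test files.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Build a fix table from coordinate/time vectors.
make_track <- function(lon, lat, times, bird_id = "b1", lc = "3") {
  data.frame(bird_id = bird_id, timestamp = times, lon = lon, lat = lat,
             lc = lc, error_radius_m = NA_real_, stringsAsFactors = FALSE)
}

# Track moving due north at a constant speed (km/h), one fix per step_h.
make_steady_track <- function(n, speed_kmh = 50, step_h = 1,
                              lon0 = -100, lat0 = 30,
                              t0 = ts_utc("2021-01-01"), bird_id = "b1") {
  dlat <- speed_kmh * step_h / 111.195
  make_track(lon = rep(lon0, n), lat = lat0 + (0:(n - 1)) * dlat,
             times = t0 + (0:(n - 1)) * step_h * 3600, bird_id = bird_id)
}

# Dynamic-programming oracle: the largest time-ordered subset that keeps the
# first fix and satisfies the pairwise-consecutive speed constraint.
dp_speed_subset <- function(track, vmax_kmh = 150) {
  n <- nrow(track)
  best_len <- rep(-Inf, n); best_len[1] <- 1
  prev <- rep(NA_integer_, n)
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      if (!is.finite(best_len[i])) next
      v <- ground_speed(track$lon[i], track$lat[i], track$timestamp[i],
                        track$lon[j], track$lat[j], track$timestamp[j])
      if (v <= vmax_kmh && best_len[i] + 1 > best_len[j]) {
        best_len[j] <- best_len[i] + 1
        prev[j] <- i
      }
    }
  }
  j <- which.max(best_len)
  path <- j
  while (!is.na(prev[j])) { j <- prev[j]; path <- c(j, path) }
  path
}

# Brute-force spatio-temporal DBSCAN oracle: all-pairs reachability graph,
# connected components over core points, borders to the earliest core
# neighbor. Mirrors the documented convention but shares no code with
# st_dbscan.
oracle_st_dbscan <- function(track, min_pts = 3, eps_m = 4000, max_lag_d = 10) {
  n <- nrow(track)
  if (n == 0) return(integer(0))
  d <- geosphere::distGeo(cbind(rep(track$lon, each = n), rep(track$lat, each = n)),
                          cbind(rep(track$lon, n), rep(track$lat, n)))
  D <- matrix(d, n, n)
  tt <- as.numeric(track$timestamp)
  A <- D <= eps_m & abs(outer(tt, tt, "-")) <= max_lag_d * 86400
  diag(A) <- TRUE
  core <- rowSums(A) >= min_pts
  comp <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || comp[i] != 0L) next
    cl <- cl + 1L
    stack <- i
    while (length(stack) > 0) {
      p <- stack[[1]]; stack <- stack[-1]
      if (comp[p] != 0L) next
      comp[p] <- cl
      nb <- which(A[p, ] & core & comp == 0L)
      stack <- c(stack, nb)
    }
  }
  for (i in which(!core)) {
    cn <- which(A[i, ] & core)
    if (length(cn) > 0) comp[i] <- comp[min(cn)]
  }
  comp
}

# Random track mixing residency bursts and jumps, for oracle equivalence.
random_oracle_track <- function(n, seed) {
  set.seed(seed)
  times <- ts_utc("2021-06-01") + cumsum(rexp(n, 1 / (6 * 3600)))
  lon <- numeric(n); lat <- numeric(n)
  cur <- c(-100 + runif(1, -2, 2), 35 + runif(1, -2, 2))
  for (i in seq_len(n)) {
    if (runif(1) < 0.15) {   # jump to a new site
      cur <- cur + runif(2, -0.5, 0.5)
    }
    lon[i] <- cur[1] + rnorm(1, 0, 0.01)
    lat[i] <- cur[2] + rnorm(1, 0, 0.01)
  }
  make_track(lon, lat, times)
}

# home_range object on an axis-aligned square grid, for exact overlap
# arithmetic: a square [x0, x0+side] x [y0, y0+side] (meters) tiled with
# cells of size cell_m.
make_square_hr <- function(x0, y0, side, cell_m = 100,
                           lon0 = -100, lat0 = 30) {
  cx <- seq(x0 + cell_m / 2, x0 + side - cell_m / 2, by = cell_m)
  cy <- seq(y0 + cell_m / 2, y0 + side - cell_m / 2, by = cell_m)
  cells <- expand.grid(x = cx, y = cy)
  ll <- trackfidelity:::laea_unproject(x0 + side / 2, y0 + side / 2, lon0, lat0)
  structure(list(cells = cells, cell_m = cell_m,
                 area_km2 = (side / 1000)^2, mass_actual = 0.9,
                 center = c(lon = ll[1, "lon"], lat = ll[1, "lat"]),
                 lon0 = lon0, lat0 = lat0),
            class = "home_range")
}

# Small simulated population shared by several test files (cached).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_birds = 3, n_years = 2, seed = 11, fix_interval_h = 8)
      cache <<- list(cfg = cfg, sim = generate_population(cfg))
    }
    cache
  }
})
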