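# Migration-route construction: regular 15-minute tracks, the population
# mean route, and per-1-degree-band entry dates and signed longitudinal
# deviations.

#' Replace clustered fixes by their cluster center
#'
#' Every fix assigned to a residency cluster takes the cluster's center
#' coordinates; timestamps and noise fixes are untouched. This removes
#' within-site jitter before route interpolation.
#'
#' @param track Single-bird fix table.
#' @param assignment Integer cluster assignment from [st_dbscan()] (0 = noise).
#' @param clusters Cluster summary table with `cluster_id`, `center_lon`,
#'   `center_lat`.
#' @return Track with substituted coordinates.
#' @export
collapse_to_centers <- function(track, assignment, clusters) {
  stopifnot(length(assignment) == nrow(track))
  for (k in seq_len(nrow(clusters))) {
    sel <- assignment == clusters$cluster_id[k]
    track$lon[sel] <- clusters$center_lon[k]
    track$lat[sel] <- clusters$center_lat[k]
  }
  track
}

# Spherical linear interpolation between two lon/lat points at fractions f.
slerp_lonlat <- function(lon1, lat1, lon2, lat2, f) {
  v1 <- lonlat_to_xyz(lon1, lat1)[1, ]
  v2 <- lonlat_to_xyz(lon2, lat2)[1, ]
  om <- acos(pmin(1, pmax(-1, sum(v1 * v2))))
  if (om < 1e-12) {
    out <- matrix(rep(v1, length(f)), ncol = 3, byrow = TRUE)
  } else {
    out <- (sin((1 - f) * om) %o% v1 + sin(f * om) %o% v2) / sin(om)
  }
  cbind(lon = atan2(out[, 2], out[, 1]) * 180 / pi,
        lat = asin(pmax(-1, pmin(1, out[, 3] / sqrt(rowSums(out^2))))) * 180 / pi)
}

#' Interpolate a track onto a regular 15-minute grid
#'
#' Produces positions every `dt_min` minutes between the first and last fix.
#' Method `"crw"` (default) runs a correlated-random-walk Kalman smoother
#' (integrated random-walk velocity model, isotropic Gaussian observation
#' error with a class-dependent standard deviation) in a local planar frame
#' and is robust to Argos noise; method `"linear"` interpolates piecewise
#' along great circles and reproduces fixes exactly. A grid position is
#' valid only when at least `min_fixes_24h` observed fixes fall within the
#' 24-hour window centered on it, so positions inside long transmission
#' gaps carry no weight in any band statistic.
#'
#' @param track Collapsed single-bird fix table with >= 2 fixes.
#' @param dt_min Grid spacing in minutes (default 15).
#' @param method `"crw"` or `"linear"`.
#' @param obs_sd_m Named vector of observation error SDs (m) per Argos class.
#' @param process_q Velocity diffusion of the CRW model (m^2/s^3).
#' @param min_fixes_24h Validity threshold (default 2).
#' @return Data.frame: bird_id, timestamp, lon, lat, valid.
#' @export
interpolate_track <- function(track, dt_min = 15, method = c("crw", "linear"),
                              obs_sd_m = c("3" = 150, "2" = 350, "1" = 800,
                                           "0" = 1500, "A" = 2500, "B" = 4000),
                              process_q = 0.05, min_fixes_24h = 2) {
  method <- match.arg(method)
  n <- nrow(track)
  if (n < 2) stop("interpolation requires at least 2 fixes")
  t0 <- track$timestamp[1]
  tn <- track$timestamp[n]
  dt_s <- dt_min * 60
  grid <- seq(from = t0, to = tn, by = dt_s)
  tg <- as.numeric(grid)
  tf <- as.numeric(track$timestamp)
  # validity: observed support in the surrounding 24 h
  nin <- vapply(tg, function(t) sum(tf >= t - 43200 & tf <= t + 43200), integer(1))
  valid <- nin >= min_fixes_24h
  if (method == "linear") {
    seg <- findInterval(tg, tf, rightmost.closed = TRUE)
    seg[seg < 1] <- 1; seg[seg >= n] <- n - 1
    pos <- matrix(NA_real_, length(tg), 2)
    for (s in unique(seg)) {
      sel <- seg == s
      f <- (tg[sel] - tf[s]) / (tf[s + 1] - tf[s])
      pos[sel, ] <- slerp_lonlat(track$lon[s], track$lat[s],
                                 track$lon[s + 1], track$lat[s + 1], f)
    }
    return(data.frame(bird_id = track$bird_id[1], timestamp = grid,
                      lon = pos[, 1], lat = pos[, 2], valid = valid,
                      stringsAsFactors = FALSE))
  }
  # CRW smoother in a local frame; x and y filtered independently
  lon0 <- mean(range(track$lon)); lat0 <- mean(range(track$lat))
  xy <- laea_project(track$lon, track$lat, lon0, lat0)
  obs_idx <- pmin(length(tg), pmax(1, round((tf - tg[1]) / dt_s) + 1))
  # one observation per grid slot: keep the fix nearest its slot time
  keep <- !duplicated(obs_idx)
  sd_map <- obs_sd_m[as.character(track$lc)]
  sd_map[is.na(sd_map)] <- 1500
  sd_map <- pmax(sd_map, 1e-3)
  obs <- rep(NA_integer_, length(tg))
  obs[obs_idx[keep]] <- which(keep)
  sm_x <- kalman_smooth_1d(xy[, 1], obs, sd_map, dt_s, process_q, length(tg))
  sm_y <- kalman_smooth_1d(xy[, 2], obs, sd_map, dt_s, process_q, length(tg))
  ll <- laea_unproject(sm_x, sm_y, lon0, lat0)
  data.frame(bird_id = track$bird_id[1], timestamp = grid,
             lon = ll[, "lon"], lat = ll[, "lat"], valid = valid,
             stringsAsFactors = FALSE)
}

# Kalman filter + RTS smoother for one axis of an integrated random-walk
# (position + velocity) model on a regular grid. obs[k] indexes the fix
# observed at grid step k (NA = none). Covariances are carried as the three
# entries of the symmetric 2x2 matrix so the per-step work is scalar.
# Returns smoothed positions.
kalman_smooth_1d <- function(z, obs, sd_obs, dt, q, nsteps) {
  q11 <- q * dt^3 / 3; q12 <- q * dt^2 / 2; q22 <- q * dt
  first_obs <- which(!is.na(obs))[1]
  fx <- numeric(nsteps); fv <- numeric(nsteps)     # filtered mean
  f11 <- numeric(nsteps); f12 <- numeric(nsteps); f22 <- numeric(nsteps)
  px <- numeric(nsteps); pv <- numeric(nsteps)     # one-step prediction
  p11 <- numeric(nsteps); p12 <- numeric(nsteps); p22 <- numeric(nsteps)
  for (k in seq_len(nsteps)) {
    if (k == 1) {
      xp <- z[obs[first_obs]]; vp <- 0
      c11 <- 1e8; c12 <- 0; c22 <- 100
    } else {
      xp <- fx[k - 1] + dt * fv[k - 1]
      vp <- fv[k - 1]
      c11 <- f11[k - 1] + 2 * dt * f12[k - 1] + dt^2 * f22[k - 1] + q11
      c12 <- f12[k - 1] + dt * f22[k - 1] + q12
      c22 <- f22[k - 1] + q22
    }
    px[k] <- xp; pv[k] <- vp
    p11[k] <- c11; p12[k] <- c12; p22[k] <- c22
    if (!is.na(obs[k])) {
      s <- c11 + sd_obs[obs[k]]^2
      k1 <- c11 / s; k2 <- c12 / s
      innov <- z[obs[k]] - xp
      fx[k] <- xp + k1 * innov
      fv[k] <- vp + k2 * innov
      f11[k] <- c11 - k1 * c11
      f12[k] <- c12 - k1 * c12
      f22[k] <- c22 - k2 * c12
    } else {
      fx[k] <- xp; fv[k] <- vp
      f11[k] <- c11; f12[k] <- c12; f22[k] <- c22
    }
  }
  sx <- fx; sv <- fv
  if (nsteps > 1) {
    for (k in (nsteps - 1):1) {
      # G = Pf %*% t(F) %*% solve(Pp[k+1]); t(F) rows: (1,0),(dt,1)
      a11 <- f11[k] + dt * f12[k]; a12 <- f12[k]
      a21 <- f12[k] + dt * f22[k]; a22 <- f22[k]
      det <- p11[k + 1] * p22[k + 1] - p12[k + 1]^2 + 1e-12
      g11 <- (a11 * p22[k + 1] - a12 * p12[k + 1]) / det
      g12 <- (-a11 * p12[k + 1] + a12 * p11[k + 1]) / det
      g21 <- (a21 * p22[k + 1] - a22 * p12[k + 1]) / det
      g22 <- (-a21 * p12[k + 1] + a22 * p11[k + 1]) / det
      dx <- sx[k + 1] - px[k + 1]; dv <- sv[k + 1] - pv[k + 1]
      sx[k] <- fx[k] + g11 * dx + g12 * dv
      sv[k] <- fv[k] + g21 * dx + g22 * dv
    }
  }
  sx
}

# Resample a polyline (lon/lat vertices) to n points equally spaced in
# cumulative great-circle distance.
resample_route <- function(lon, lat, n) {
  m <- length(lon)
  if (m == 1) {
    return(cbind(lon = rep(lon, n), lat = rep(lat, n)))
  }
  d <- geosphere::distGeo(cbind(lon[-m], lat[-m]), cbind(lon[-1], lat[-1]))
  cum <- c(0, cumsum(d))
  if (cum[m] < 1e-9) {
    return(cbind(lon = rep(lon[1], n), lat = rep(lat[1], n)))
  }
  target <- seq(0, cum[m], length.out = n)
  seg <- findInterval(target, cum, rightmost.closed = TRUE)
  seg[seg >= m] <- m - 1
  out <- matrix(NA_real_, n, 2)
  for (s in unique(seg)) {
    sel <- seg == s
    f <- (target[sel] - cum[s]) / max(cum[s + 1] - cum[s], 1e-12)
    out[sel, ] <- slerp_lonlat(lon[s], lat[s], lon[s + 1], lat[s + 1], f)
  }
  colnames(out) <- c("lon", "lat")
  out
}

# For each query point (3D rows), index of the nearest vertex of V (3D rows).
nearest_vertex <- function(Vxyz, Qxyz) {
  max.col(Qxyz %*% t(Vxyz), ties.method = "first")
}

# Greedy minimum-spacing thinning of a polyline: drop vertices closer than
# thin_m (geodesic) to the last kept vertex. Keeps flight-leg geometry
# intact while collapsing stationary residency clouds, which would
# otherwise dominate nearest-point averages by sheer vertex count.
thin_polyline <- function(p, thin_m) {
  n <- nrow(p)
  if (n <= 2 || thin_m <= 0) return(p)
  d <- geosphere::distGeo(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
  keep <- logical(n)
  keep[1] <- TRUE
  acc <- 0
  for (i in 2:n) {
    acc <- acc + d[i - 1]
    if (acc >= thin_m) { keep[i] <- TRUE; acc <- 0 }
  }
  keep[n] <- TRUE
  p[keep, , drop = FALSE]
}

#' Population mean migration route
#'
#' Averages a set of migration tracks into one route of `n` ordered points
#' placed so that the distance to the nearest locations on the individual
#' tracks is minimized. The route is initialized as the pointwise average
#' of the tracks resampled to `n` points by cumulative-distance fraction,
#' then refined iteratively: each route point moves to the average of the
#' nearest point on every track, the polyline is re-spaced to `n` points,
#' and the objective (mean over route points of the mean nearest-track
#' distance) is re-evaluated. Iteration stops when the mean point
#' displacement drops below `tol_km` or when a step fails to improve the
#' objective (the previous route is kept, so the recorded objective trace
#' is non-increasing).
#'
#' @param tracks List of interpolated tracks (data.frames with lon, lat and
#'   optionally valid); invalid positions are ignored.
#' @param n Number of route points (default 500).
#' @param direction "south" or "north" (metadata only).
#' @param tol_km Convergence tolerance on mean point displacement (km).
#' @param max_iter Iteration cap.
#' @param thin_m Minimum vertex spacing (m) applied to the input tracks
#'   before averaging, so stationary stopover clouds do not dominate the
#'   nearest-point averages; 0 disables.
#' @return List of class `mean_route`: `points` (n x 2 lon/lat), `direction`,
#'   `objective_km` (trace, non-increasing), `n_iter`.
#' @export
mean_route <- function(tracks, n = 500, direction = c("south", "north"),
                       tol_km = 1, max_iter = 100, thin_m = 1000) {
  direction <- match.arg(direction)
  pts <- lapply(tracks, function(tr) {
    if ("valid" %in% names(tr)) tr <- tr[tr$valid, , drop = FALSE]
    thin_polyline(cbind(tr$lon, tr$lat), thin_m)
  })
  pts <- pts[vapply(pts, nrow, integer(1)) >= 2]
  if (length(pts) == 0) stop("mean_route needs at least one usable track")
  res <- lapply(pts, function(p) resample_route(p[, 1], p[, 2], n))
  route <- cbind(lon = rowMeans(sapply(res, `[`, , 1)),
                 lat = rowMeans(sapply(res, `[`, , 2)))
  # the route must span the full course of migration: its endpoints stay
  # anchored at the mean track start/end, otherwise the nearest-point
  # objective is minimized by contracting the route into the densest part
  # of the corridor
  p_start <- colMeans(do.call(rbind, lapply(pts, function(p) p[1, ])))
  p_end <- colMeans(do.call(rbind, lapply(pts, function(p) p[nrow(p), ])))
  txyz <- lapply(pts, function(p) lonlat_to_xyz(p[, 1], p[, 2]))
  objective <- function(r) {
    q <- lonlat_to_xyz(r[, 1], r[, 2])
    dsum <- 0
    for (i in seq_along(pts)) {
      nv <- nearest_vertex(txyz[[i]], q)
      dsum <- dsum + mean(geosphere::distGeo(r, pts[[i]][nv, , drop = FALSE]))
    }
    dsum / length(pts) / 1000
  }
  obj <- objective(route)
  trace <- obj
  n_iter <- 0
  if (length(pts) > 1) {
    for (it in seq_len(max_iter)) {
      q <- lonlat_to_xyz(route[, 1], route[, 2])
      acc <- matrix(0, n, 2)
      for (i in seq_along(pts)) {
        nv <- nearest_vertex(txyz[[i]], q)
        acc <- acc + pts[[i]][nv, , drop = FALSE]
      }
      poly <- acc / length(pts)
      poly[1, ] <- p_start
      poly[n, ] <- p_end
      newroute <- resample_route(poly[, 1], poly[, 2], n)
      newobj <- objective(newroute)
      if (newobj > obj + 1e-9) break       # keep the previous (better) route
      disp <- mean(geosphere::distGeo(route, newroute)) / 1000
      route <- newroute
      obj <- newobj
      trace <- c(trace, newobj)
      n_iter <- it
      if (disp < tol_km) break
    }
  }
  structure(list(points = as.data.frame(route), direction = direction,
                 objective_km = trace, n_iter = n_iter),
            class = "mean_route")
}

.BAND_RANGE <- c(8L, 72L)   # 1-degree band low latitudes, 8N..72N inclusive

#' First entry date into each 1-degree latitudinal band
#'
#' For each band (low latitude 8..72 N) the timestamp of the first valid
#' interpolated position whose latitude falls inside the band; bands never
#' entered are absent, re-entries after wandering are ignored.
#'
#' @param it Interpolated track (one bird-year, one direction).
#' @param cycle_year Cycle-year label attached to the observations.
#' @param direction "south" or "north".
#' @return Data.frame: bird_id, cycle_year, direction, band_low_lat,
#'   kind = "entry_date", value (fractional day of year of first entry).
#' @export
band_entry_dates <- function(it, cycle_year = NA_integer_,
                             direction = c("south", "north")) {
  direction <- match.arg(direction)
  v <- it[it$valid, , drop = FALSE]
  if (nrow(v) == 0) return(empty_band_obs())
  band <- floor(v$lat)
  ok <- band >= .BAND_RANGE[1] & band <= .BAND_RANGE[2]
  v <- v[ok, , drop = FALSE]; band <- band[ok]
  if (nrow(v) == 0) return(empty_band_obs())
  first <- !duplicated(band)
  t <- v$timestamp[first]
  doy <- as.numeric(difftime(t, as.POSIXct(paste0(format(t, "%Y", tz = "UTC"),
                                                  "-01-01"), tz = "UTC"),
                             units = "days"))
  data.frame(bird_id = v$bird_id[1], cycle_year = cycle_year,
             direction = direction, band_low_lat = band[first],
             kind = "entry_date", value = doy, stringsAsFactors = FALSE)
}

empty_band_obs <- function() {
  data.frame(bird_id = character(), cycle_year = integer(),
             direction = character(), band_low_lat = integer(),
             kind = character(), value = numeric(), stringsAsFactors = FALSE)
}

#' Signed longitudinal deviation from the mean route, per band
#'
#' For every mean-route point, the signed east-west geodesic distance (km,
#' west negative) from the route point to the nearest valid position on the
#' individual track, averaged within each 1-degree latitudinal band of the
#' route point.
#'
#' @param it Interpolated track (one bird-year).
#' @param mr A [mean_route()] object.
#' @param cycle_year,direction Labels attached to the observations.
#' @return Data.frame in the same shape as [band_entry_dates()], with
#'   kind = "lon_deviation" and value in km.
#' @export
band_lon_deviation <- function(it, mr, cycle_year = NA_integer_,
                               direction = c("south", "north")) {
  direction <- match.arg(direction)
  v <- it[it$valid, , drop = FALSE]
  if (nrow(v) == 0) return(empty_band_obs())
  rp <- as.matrix(mr$points)
  nv <- nearest_vertex(lonlat_to_xyz(v$lon, v$lat),
                       lonlat_to_xyz(rp[, 1], rp[, 2]))
  dev_km <- signed_ew_dist_m(v$lon[nv], rp[, 1], rp[, 2]) / 1000
  band <- floor(rp[, 2])
  ok <- band >= .BAND_RANGE[1] & band <= .BAND_RANGE[2]
  if (!any(ok)) return(empty_band_obs())
  agg <- tapply(dev_km[ok], band[ok], mean)
  data.frame(bird_id = v$bird_id[1], cycle_year = cycle_year,
             direction = direction,
             band_low_lat = as.integer(names(agg)),
             kind = "lon_deviation", value = as.numeric(agg),
             stringsAsFactors = FALSE)
}
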