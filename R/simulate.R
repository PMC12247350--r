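# Synthetic Argos-track generator with known ground truth.
#
# Emulates a satellite-tracked Arctic-breeding shorebird population:
# two flyways; one wintering site per bird reused every year with small
# jitter (high wintering fidelity); a fresh breeding site each year drawn
# from a dispersal kernel (low breeding fidelity); an extended molt-staging
# stopover plus shorter stops on southward migration; short or no stops on
# northward migration; great-circle flight legs at a realistic airspeed;
# Argos class-dependent positional error; and per-event timing that follows
# a random-intercept model with configurable true repeatability
# R_true = sigma2_between / (sigma2_between + sigma2_within).

.DEG_KM <- 111.195  # km per degree of latitude (spherical)

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the package is validated
#' against: a 2-flyway population, breeding dispersal averaging ~159 km
#' between consecutive years (2-D Gaussian kernel, sd 127 km per axis),
#' near-exact wintering-site reuse (3 km jitter), a long molt-staging
#' stopover at mid-latitudes on the way south, and timing repeatability
#' R_true = 8^2 / (8^2 + 6^2) = 0.64 for every range event.
#'
#' @param n_birds Number of birds (>= 2).
#' @param n_years Number of tracked annual cycles per bird (>= 2).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param breeding_polygon,wintering_polygon Polygon vertex matrices
#'   (lon, lat); defaults from [generate_range_polygons()].
#' @param breeding_dispersal_sd_km Per-axis sd of the year-to-year breeding
#'   dispersal kernel (km).
#' @param wintering_dispersal_sd_km Per-axis sd of the annual jitter around
#'   a bird's fixed wintering site (km).
#' @param n_stopovers_mean Mean number of southbound stopovers (>= 1 drawn).
#' @param flight_speed_kmh Ground speed on migration legs.
#' @param fix_interval_h Argos fix interval (hours).
#' @param timing_sigma_between_d,timing_sigma_within_d Between- and
#'   within-individual sd (days) of the range-event dates; a scalar applies
#'   to all four events, or a named vector over `breeding_arrival`,
#'   `breeding_departure`, `wintering_arrival`, `wintering_departure` sets
#'   them per event (e.g. to anchor timing consistency on the wintering
#'   area).
#' @param argos_class_probs Named probabilities over classes 3,2,1,0,A,B.
#' @param argos_error_sd_m Named per-class isotropic error sd (m).
#' @param p_central_flyway Probability a bird uses the central flyway.
#' @param site_scatter_km Within-residency movement sd (km).
#' @param approach_meander_mean_d Mean extra days (exponential) spent on the
#'   slow final approach from the last southbound stopover to the wintering
#'   site; decouples the end of staging from wintering arrival, as in real
#'   populations where birds drift through coastal sites before settling.
#' @param fixes_per_burst_mean Mean fixes per transmission burst; Argos
#'   duty cycles deliver 1+ fixes within ~30 min of each scheduled uplink.
#' @param outlier_prob Probability a fix is a gross location error.
#' @param outlier_factor Gross errors are drawn with `outlier_factor` times
#'   the fix's class error sd (so a zero-error configuration stays exact).
#' @param dropout_prob Uniform fix dropout probability.
#' @param start_year First cycle year.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_birds = 20, n_years = 3, seed = 1,
                       breeding_polygon = NULL, wintering_polygon = NULL,
                       breeding_dispersal_sd_km = 127,
                       wintering_dispersal_sd_km = 3,
                       n_stopovers_mean = 2,
                       flight_speed_kmh = 70,
                       fix_interval_h = 6,
                       timing_sigma_between_d = 8,
                       timing_sigma_within_d = 6,
                       argos_class_probs = c("3" = 0.08, "2" = 0.12, "1" = 0.14,
                                             "0" = 0.19, "A" = 0.23, "B" = 0.24),
                       argos_error_sd_m = c("3" = 150, "2" = 350, "1" = 800,
                                            "0" = 1500, "A" = 2500, "B" = 4000),
                       p_central_flyway = 0.85,
                       site_scatter_km = 1,
                       approach_meander_mean_d = 6,
                       fixes_per_burst_mean = 1.5,
                       outlier_prob = 0.02,
                       outlier_factor = 25,
                       dropout_prob = 0,
                       start_year = 2020) {
  if (is.null(breeding_polygon) || is.null(wintering_polygon)) {
    rp <- generate_range_polygons()
    if (is.null(breeding_polygon)) breeding_polygon <- rp$breeding
    if (is.null(wintering_polygon)) wintering_polygon <- rp$wintering
  }
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Study-condition simulation configuration
#'
#' The reference synthetic study the package is validated against: a
#' 20-bird, 3-year population with strong wintering fidelity (3 km site
#' jitter), wide breeding dispersal (127 km/axis kernel), and
#' wintering-anchored timing — between-individual timing sd of 10 d for
#' wintering arrival against 3 d for the breeding events (within-individual
#' sd 6 d throughout), so that true timing repeatability is highest at
#' arrival on the wintering grounds (R_true = 0.74 there vs 0.20 at the
#' breeding events).
#'
#' @param seed Integer seed.
#' @param n_birds,n_years Population size and tracked cycles.
#' @return A [sim_config()].
#' @export
study_sim_config <- function(seed = 1, n_birds = 20, n_years = 3) {
  sim_config(
    n_birds = n_birds, n_years = n_years, seed = seed,
    timing_sigma_between_d = c(breeding_arrival = 3, breeding_departure = 3,
                               wintering_arrival = 10, wintering_departure = 5),
    timing_sigma_within_d = 6)
}

# Scalar -> per-event vector; named vectors are matched by event name.
expand_event_sigma <- function(x, events) {
  if (length(x) == 1) return(stats::setNames(rep(x, length(events)), events))
  if (is.null(names(x)) || !all(events %in% names(x))) {
    stop("per-event timing sigmas must be named over: ",
         paste(events, collapse = ", "))
  }
  x[events]
}

validate_sim_config <- function(cfg) {
  if (cfg$n_birds < 2) stop("n_birds must be >= 2")
  if (cfg$n_years < 2) stop("n_years must be >= 2")
  events <- c("breeding_arrival", "breeding_departure",
              "wintering_arrival", "wintering_departure")
  expand_event_sigma(cfg$timing_sigma_between_d, events)
  expand_event_sigma(cfg$timing_sigma_within_d, events)
  if (abs(sum(cfg$argos_class_probs) - 1) > 1e-8) {
    stop("argos_class_probs must sum to 1")
  }
  if (!setequal(names(cfg$argos_class_probs), c("3", "2", "1", "0", "A", "B"))) {
    stop("argos_class_probs must be named over classes 3,2,1,0,A,B")
  }
  sds <- c(cfg$breeding_dispersal_sd_km, cfg$wintering_dispersal_sd_km,
           cfg$timing_sigma_between_d, cfg$timing_sigma_within_d,
           cfg$argos_error_sd_m, cfg$site_scatter_km)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  if (cfg$fixes_per_burst_mean < 1) stop("fixes_per_burst_mean must be >= 1")
  if (cfg$outlier_prob < 0 || cfg$outlier_prob > 1) {
    stop("outlier_prob must be in [0, 1]")
  }
  if (min(cfg$breeding_polygon[, 2]) <= max(cfg$wintering_polygon[, 2])) {
    stop("breeding and wintering polygons must be disjoint, ",
         "breeding north of wintering")
  }
  invisible(cfg)
}

#' Default breeding and wintering range polygons
#'
#' Two disjoint convex polygons (counter-clockwise rings) separated in
#' latitude: an Arctic breeding range and a southern-US/Mexico wintering
#' range; synthetic stand-ins sized like the real species ranges.
#'
#' @return List with `breeding` and `wintering` vertex matrices (lon, lat).
#' @export
generate_range_polygons <- function() {
  breeding <- cbind(lon = c(-166, -144, -144, -166),
                    lat = c(67.5, 67.5, 72.5, 72.5))
  wintering <- cbind(lon = c(-126, -94, -94, -126),
                     lat = c(21.5, 21.5, 32.5, 32.5))
  list(breeding = breeding, wintering = wintering)
}

# Move a lon/lat point by (de, dn) kilometers east/north.
.offset_km <- function(lon, lat, de_km, dn_km) {
  lat2 <- lat + dn_km / .DEG_KM
  lon2 <- lon + de_km / (.DEG_KM * cos(lat * pi / 180))
  c(lon2, lat2)
}

.doy_time <- function(year, doy) {
  as.POSIXct(paste0(year, "-01-01 00:00:00"), tz = "UTC") + doy * 86400
}

#' Generate a synthetic tracked population
#'
#' Builds, for every bird and cycle year, a behavioral itinerary (breeding
#' residency, southbound stopovers, wintering residency, northbound
#' stopovers, great-circle flight legs), samples Argos-like fixes along it
#' at the configured interval, and perturbs them with class-dependent
#' isotropic Gaussian error. Event dates follow
#' `population mean + bird intercept + annual noise`. Deterministic given
#' `cfg$seed`; the global RNG state is left untouched.
#'
#' @param cfg A [sim_config()].
#' @return List with `fixes` (Argos fix table), and `truth`: `segments`
#'   (per-fix: type residency/flight, stage, site id, true lon/lat),
#'   `birds` (flyway, wintering site, timing intercepts), `breeding_sites`
#'   (per bird-year), `stopovers`, `events` (per bird-year realized event
#'   days of year), and `R_true`.
#' @export
generate_population <- function(cfg) {
  validate_sim_config(cfg)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  events <- c("breeding_arrival", "breeding_departure",
              "wintering_arrival", "wintering_departure")
  mean_doy <- c(breeding_arrival = 152, breeding_departure = 198,
                wintering_arrival = 289, wintering_departure = 120)
  bp <- cfg$breeding_polygon
  wp <- cfg$wintering_polygon
  sig_b <- expand_event_sigma(cfg$timing_sigma_between_d, events)
  sig_w <- expand_event_sigma(cfg$timing_sigma_within_d, events)
  tot <- sig_b^2 + sig_w^2
  R_true <- ifelse(tot > 0, sig_b^2 / tot, 0)
  names(R_true) <- events

  fixes_l <- list(); seg_l <- list()
  birds_l <- list(); bsites_l <- list(); stops_l <- list(); events_l <- list()

  for (b in seq_len(cfg$n_birds)) {
    bid <- sprintf("bird%02d", b)
    central <- stats::runif(1) < cfg$p_central_flyway
    wlon_rng <- if (central) c(-106, -95) else c(-125, -116)
    wsite <- c(stats::runif(1, wlon_rng[1], wlon_rng[2]),
               stats::runif(1, min(wp[, 2]) + 1, max(wp[, 2]) - 1))
    icpt <- stats::rnorm(length(events), 0, sig_b)
    names(icpt) <- events
    birds_l[[b]] <- data.frame(bird_id = bid, flyway = if (central) "central" else "pacific",
                               wintering_lon = wsite[1], wintering_lat = wsite[2],
                               t(icpt), stringsAsFactors = FALSE)

    # breeding sites: year 1 uniform, then a Gaussian dispersal kernel,
    # resampled until inside the breeding range
    bsites <- matrix(NA_real_, cfg$n_years, 2)
    bsites[1, ] <- c(stats::runif(1, min(bp[, 1]) + 0.5, max(bp[, 1]) - 0.5),
                     stats::runif(1, min(bp[, 2]) + 0.3, max(bp[, 2]) - 0.3))
    if (cfg$n_years > 1) {
      for (y in 2:cfg$n_years) {
        for (try in 1:200) {
          cand <- .offset_km(bsites[y - 1, 1], bsites[y - 1, 2],
                             stats::rnorm(1, 0, cfg$breeding_dispersal_sd_km),
                             stats::rnorm(1, 0, cfg$breeding_dispersal_sd_km))
          if (point_in_polygon(cand[1], cand[2], bp)) break
        }
        if (!point_in_polygon(cand[1], cand[2], bp)) cand <- bsites[y - 1, ]
        bsites[y, ] <- cand
      }
    }
    bsites_l[[b]] <- data.frame(bird_id = bid,
                                cycle_year = cfg$start_year + seq_len(cfg$n_years) - 1,
                                lon = bsites[, 1], lat = bsites[, 2],
                                stringsAsFactors = FALSE)

    # event dates per cycle year
    ev <- matrix(NA_real_, cfg$n_years + 1, length(events),
                 dimnames = list(NULL, events))
    for (y in seq_len(cfg$n_years + 1)) {
      ev[y, ] <- mean_doy + icpt + stats::rnorm(length(events), 0, sig_w)
    }
    # itinerary: list of residency segments (site, start, end, stage, id)
    segs <- list()
    add_seg <- function(stage, site, start, end, sid) {
      segs[[length(segs) + 1]] <<- list(stage = stage, site = site,
                                        start = start, end = end, sid = sid)
    }
    for (y in seq_len(cfg$n_years)) {
      yr <- cfg$start_year + y - 1
      bsite <- bsites[y, ]
      wsite_y <- .offset_km(wsite[1], wsite[2],
                            stats::rnorm(1, 0, cfg$wintering_dispersal_sd_km),
                            stats::rnorm(1, 0, cfg$wintering_dispersal_sd_km))
      t_ba <- .doy_time(yr, ev[y, "breeding_arrival"])
      t_bd <- .doy_time(yr, max(ev[y, "breeding_departure"],
                                ev[y, "breeding_arrival"] + 10))
      t_wa <- .doy_time(yr, max(ev[y, "wintering_arrival"],
                                ev[y, "breeding_departure"] + 15))
      add_seg("breeding", bsite, t_ba, t_bd, sprintf("%s_breed_%d", bid, yr))

      # southbound: molt-staging stop plus shorter stops
      n_s <- max(1L, stats::rpois(1, cfg$n_stopovers_mean))
      route <- plan_migration(bsite, wsite_y, n_s, cfg$flight_speed_kmh,
                              t_bd, t_wa, long_first = TRUE,
                              meander_mean_d = cfg$approach_meander_mean_d)
      for (k in seq_along(route$stops)) {
        add_seg("south_stopover", route$stops[[k]]$site,
                route$stops[[k]]$start, route$stops[[k]]$end,
                sprintf("%s_sstop_%d_%d", bid, yr, k))
        stops_l[[length(stops_l) + 1]] <- data.frame(
          bird_id = bid, cycle_year = yr, direction = "south", k = k,
          lon = route$stops[[k]]$site[1], lat = route$stops[[k]]$site[2],
          stringsAsFactors = FALSE)
      }
      t_wa_real <- route$arrival
      # wintering: to next spring's departure, or a truncated final winter
      if (y < cfg$n_years) {
        t_wd <- .doy_time(yr + 1, ev[y + 1, "wintering_departure"])
        add_seg("wintering", wsite_y, t_wa_real, t_wd,
                sprintf("%s_winter_%d", bid, yr))
        # northbound to next year's breeding site
        t_ba_next <- .doy_time(yr + 1, ev[y + 1, "breeding_arrival"])
        if (as.numeric(difftime(t_ba_next, t_wd, units = "days")) < 10) {
          t_ba_next <- t_wd + 10 * 86400
        }
        # at least one (usually short) stop so the leg can absorb the time
        # between wintering departure and the target breeding arrival
        n_n <- max(1L, stats::rpois(1, 0.7))
        route_n <- plan_migration(wsite_y, bsites[min(y + 1, cfg$n_years), ],
                                  n_n, cfg$flight_speed_kmh, t_wd, t_ba_next,
                                  long_first = FALSE)
        for (k in seq_along(route_n$stops)) {
          add_seg("north_stopover", route_n$stops[[k]]$site,
                  route_n$stops[[k]]$start, route_n$stops[[k]]$end,
                  sprintf("%s_nstop_%d_%d", bid, yr + 1, k))
          stops_l[[length(stops_l) + 1]] <- data.frame(
            bird_id = bid, cycle_year = yr + 1, direction = "north", k = k,
            lon = route_n$stops[[k]]$site[1], lat = route_n$stops[[k]]$site[2],
            stringsAsFactors = FALSE)
        }
        ev[y + 1, "breeding_arrival"] <- as.numeric(
          difftime(route_n$arrival, .doy_time(yr + 1, 0), units = "days"))
      } else {
        # final winter: track ends at that season's true departure date
        t_wd <- .doy_time(yr + 1, ev[y + 1, "wintering_departure"])
        add_seg("wintering", wsite_y, t_wa_real, t_wd,
                sprintf("%s_winter_%d", bid, yr))
      }
      ev[y, "wintering_arrival"] <- as.numeric(
        difftime(t_wa_real, .doy_time(yr, 0), units = "days"))
      events_l[[length(events_l) + 1]] <- data.frame(
        bird_id = bid, cycle_year = yr,
        event = events,
        value = c(ev[y, "breeding_arrival"], ev[y, "breeding_departure"],
                  ev[y, "wintering_arrival"], ev[y + 1, "wintering_departure"]),
        stringsAsFactors = FALSE)
    }

    bird_out <- sample_fixes(segs, cfg, bid)
    fixes_l[[b]] <- bird_out$fixes
    seg_l[[b]] <- bird_out$segments
  }

  fixes <- do.call(rbind, c(fixes_l, list(make.row.names = FALSE)))
  segments <- do.call(rbind, c(seg_l, list(make.row.names = FALSE)))
  if (cfg$dropout_prob > 0) {
    keep <- stats::runif(nrow(fixes)) >= cfg$dropout_prob
    fixes <- fixes[keep, , drop = FALSE]
    segments <- segments[keep, , drop = FALSE]
  }
  list(fixes = fixes,
       truth = list(
         segments = segments,
         birds = do.call(rbind, c(birds_l, list(make.row.names = FALSE))),
         breeding_sites = do.call(rbind, c(bsites_l, list(make.row.names = FALSE))),
         stopovers = if (length(stops_l) > 0)
           do.call(rbind, c(stops_l, list(make.row.names = FALSE))) else NULL,
         events = do.call(rbind, c(events_l, list(make.row.names = FALSE))),
         R_true = R_true))
}

# Lay out a migration from `from` to `to` with n_stop stopovers between
# departure t0 and target arrival t1. Stopover sites sit on the great
# circle at sorted random fractions with cross-track jitter, constrained
# to the mid-latitude staging belt (so stops never fall inside the
# breeding or wintering ranges); flight legs run at `speed_kmh`; stopover
# durations fill the remaining time (the first stop takes 70% when
# `long_first`, emulating extended molt staging). If the window cannot
# hold the stops they are shortened or dropped; the realized arrival time
# is returned.
plan_migration <- function(from, to, n_stop, speed_kmh, t0, t1, long_first,
                           stop_lat_range = c(33.5, 60), meander_mean_d = 0) {
  window_d <- as.numeric(difftime(t1, t0, units = "days"))
  # variable slow final approach: consumes part of the window after the
  # last stopover, so the end of staging is not a deterministic offset of
  # the arrival date
  meander_d <- if (meander_mean_d > 0) stats::rexp(1, 1 / meander_mean_d) else 0
  repeat {
    if (n_stop > 0) {
      fr <- sort(stats::runif(n_stop, 0.15, 0.85))
      sites <- lapply(fr, function(f) {
        p <- slerp_lonlat(from[1], from[2], to[1], to[2], f)
        s <- .offset_km(p[1, "lon"], p[1, "lat"], stats::rnorm(1, 0, 50),
                        stats::rnorm(1, 0, 30))
        s[2] <- min(max(s[2], stop_lat_range[1]), stop_lat_range[2])
        s
      })
    } else {
      sites <- list()
    }
    way <- c(list(from), sites, list(to))
    d_km <- vapply(seq_len(length(way) - 1), function(i) {
      geosphere::distGeo(way[[i]], way[[i + 1]]) / 1000
    }, numeric(1))
    flight_d <- sum(d_km) / speed_kmh / 24
    slack_d <- window_d - flight_d
    if (slack_d >= 0.5 * n_stop || n_stop == 0) break
    n_stop <- n_stop - 1
  }
  meander_d <- min(meander_d, 0.5 * max(slack_d, 0))
  budget_d <- slack_d - meander_d
  if (n_stop > 0) {
    w <- if (long_first && n_stop > 1) {
      c(0.7, rep(0.3 / (n_stop - 1), n_stop - 1))
    } else {
      rep(1 / n_stop, n_stop)
    }
    dur <- pmax(0.5, w * max(budget_d, 0.5 * n_stop))
  } else {
    dur <- numeric(0)
  }
  stops <- list()
  t <- t0
  leg_d <- vapply(seq_len(length(way) - 1), function(i) {
    geosphere::distGeo(way[[i]], way[[i + 1]]) / 1000
  }, numeric(1))
  for (k in seq_len(n_stop)) {
    t_arr <- t + leg_d[k] / speed_kmh * 3600
    t_dep <- t_arr + dur[k] * 86400
    stops[[k]] <- list(site = way[[k + 1]], start = t_arr, end = t_dep)
    t <- t_dep
  }
  arrival <- t + leg_d[length(leg_d)] / speed_kmh * 3600 + meander_d * 86400
  list(stops = stops, arrival = arrival)
}

# Sample Argos fixes along a bird's itinerary of residency segments with
# great-circle flight legs between them.
sample_fixes <- function(segs, cfg, bid) {
  t_start <- segs[[1]]$start
  t_end <- segs[[length(segs)]]$end
  bursts <- seq(from = t_start, to = t_end, by = cfg$fix_interval_h * 3600)
  k <- 1L + stats::rpois(length(bursts), max(0, cfg$fixes_per_burst_mean - 1))
  tt <- rep(bursts, k) + stats::runif(sum(k), 0, 1800)
  tt <- sort(tt)
  tt <- tt[c(TRUE, diff(as.numeric(tt)) >= 1)]   # strictly increasing
  n <- length(tt)
  lon <- numeric(n); lat <- numeric(n)
  type <- character(n); stage <- character(n); sid <- character(n)
  seg_starts <- as.numeric(vapply(segs, function(s) as.numeric(s$start), numeric(1)))
  seg_ends <- as.numeric(vapply(segs, function(s) as.numeric(s$end), numeric(1)))
  tn <- as.numeric(tt)
  seg_idx <- findInterval(tn, seg_starts)
  seg_idx[seg_idx < 1L] <- 1L
  for (i in seq_len(n)) {
    cur <- seg_idx[i]
    s <- segs[[cur]]
    if (tn[i] <= seg_ends[cur]) {
      p <- .offset_km(s$site[1], s$site[2],
                      stats::rnorm(1, 0, cfg$site_scatter_km),
                      stats::rnorm(1, 0, cfg$site_scatter_km))
      lon[i] <- p[1]; lat[i] <- p[2]
      type[i] <- "residency"; stage[i] <- res_stage(s$stage); sid[i] <- s$sid
    } else {
      # flight leg from segment cur to cur + 1
      nxt <- segs[[min(cur + 1L, length(segs))]]
      f <- (tn[i] - seg_ends[cur]) / max(seg_starts[min(cur + 1L, length(segs))] -
                                           seg_ends[cur], 1)
      f <- min(1, max(0, f))
      p <- slerp_lonlat(s$site[1], s$site[2], nxt$site[1], nxt$site[2], f)
      lon[i] <- p[1, "lon"]; lat[i] <- p[1, "lat"]
      type[i] <- "flight"
      stage[i] <- flight_stage(s$stage, nxt$stage)
      sid[i] <- ""
    }
  }
  lc <- sample(names(cfg$argos_class_probs), n, replace = TRUE,
               prob = cfg$argos_class_probs)
  err_sd <- cfg$argos_error_sd_m[lc]
  # occasional gross location errors, scaled to the fix's class error
  gross <- stats::runif(n) < cfg$outlier_prob
  err_sd[gross] <- err_sd[gross] * cfg$outlier_factor
  de <- stats::rnorm(n, 0, err_sd) / 1000
  dn <- stats::rnorm(n, 0, err_sd) / 1000
  obs_lat <- lat + dn / .DEG_KM
  obs_lon <- lon + de / (.DEG_KM * cos(lat * pi / 180))
  fixes <- data.frame(
    bird_id = bid, timestamp = tt, lon = obs_lon, lat = obs_lat, lc = lc,
    error_radius_m = ifelse(lc %in% c("A", "B"), NA_real_,
                            as.numeric(cfg$argos_error_sd_m[lc])),
    stringsAsFactors = FALSE)
  segments <- data.frame(bird_id = bid, timestamp = tt, true_lon = lon,
                         true_lat = lat, type = type, stage = stage,
                         site_id = sid, stringsAsFactors = FALSE)
  list(fixes = fixes, segments = segments)
}

res_stage <- function(seg_stage) {
  switch(seg_stage,
         breeding = "breeding", wintering = "wintering",
         south_stopover = "south_migration", north_stopover = "north_migration")
}

flight_stage <- function(from_stage, to_stage) {
  if (from_stage == "breeding" || to_stage %in% c("south_stopover", "wintering")) {
    return("south_migration")
  }
  "north_migration"
}
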