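# End-to-end orchestration: simulate (or load) -> filter -> segment ->
# cluster -> home ranges -> routes -> repeatability -> stage models.

#' Pipeline configuration
#'
#' Collects every tunable parameter with its default: 150 km/h speed
#' filter; clustering MinPts 3 / eps 4000 m / maxLag 10 d (alternative
#' preset 5 / 8000 / 20 via `cluster_preset = "coarse"`); tenure > 1 d;
#' 90% UD level; 15-min interpolation; 500 mean-route points; 1-degree
#' bands from 8N; bootstrap iterations; seed. Unknown arguments are
#' rejected.
#'
#' @param vmax_kmh Speed-filter threshold (km/h).
#' @param cluster_preset "default" (3 / 4000 m / 10 d) or "coarse"
#'   (5 / 8000 m / 20 d).
#' @param min_pts,eps_m,max_lag_d Explicit clustering overrides.
#' @param min_tenure_d Residency tenure threshold (strict, days).
#' @param ud_level Utilization-distribution level.
#' @param dt_min Interpolation grid (minutes).
#' @param interp_method "crw" or "linear".
#' @param n_route_points Mean-route points.
#' @param n_boot Bootstrap iterations for repeatability.
#' @param seed Seed for all stochastic steps.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(vmax_kmh = 150, cluster_preset = c("default", "coarse"),
                            min_pts = NULL, eps_m = NULL, max_lag_d = NULL,
                            min_tenure_d = 1, ud_level = 0.90, dt_min = 15,
                            interp_method = c("crw", "linear"),
                            n_route_points = 500, n_boot = 1000, seed = 1) {
  cluster_preset <- match.arg(cluster_preset)
  interp_method <- match.arg(interp_method)
  preset <- if (cluster_preset == "default") {
    list(min_pts = 3, eps_m = 4000, max_lag_d = 10)
  } else {
    list(min_pts = 5, eps_m = 8000, max_lag_d = 20)
  }
  structure(list(
    vmax_kmh = vmax_kmh,
    min_pts = if (is.null(min_pts)) preset$min_pts else min_pts,
    eps_m = if (is.null(eps_m)) preset$eps_m else eps_m,
    max_lag_d = if (is.null(max_lag_d)) preset$max_lag_d else max_lag_d,
    min_tenure_d = min_tenure_d, ud_level = ud_level, dt_min = dt_min,
    interp_method = interp_method, n_route_points = n_route_points,
    n_boot = n_boot, seed = seed), class = "pipeline_config")
}

#' Run the full annual-cycle fidelity analysis
#'
#' @param fixes Argos fix table (e.g. from [generate_population()] or
#'   [read_fixes()]).
#' @param breeding_poly,wintering_poly Range polygons (vertex matrices).
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, intermediate CSV tables
#'   are written there.
#' @return List with every intermediate product: `filter` (kept/removed),
#'   `intervals`, `clusters` (annotated, tenure-filtered), `home_ranges`,
#'   `fidelity`, `models` (overlap ZIB + distance Gaussian), `routes`
#'   (interpolated tracks, mean routes), `band_obs`, `profiles`,
#'   `events`, `event_rpt`, and `summary` (per-stage residency counts,
#'   home-range medians, overlap incidence).
#' @export
run_pipeline <- function(fixes, breeding_poly, wintering_poly,
                         cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_msg <- function(...) message("[pipeline] ", ...)

  log_msg("speed filter at ", cfg$vmax_kmh, " km/h")
  flt <- filter_fixes(fixes, vmax_kmh = cfg$vmax_kmh)
  log_msg(nrow(flt$removed), " of ", nrow(fixes), " fixes removed (",
          round(100 * flt$removed_fraction, 1), "%)")

  tracks <- split_tracks(flt$kept)
  all_intervals <- list(); all_clusters <- list()
  assignments <- list()
  for (bid in names(tracks)) {
    tr <- tracks[[bid]]
    db <- st_dbscan(tr, min_pts = cfg$min_pts, eps_m = cfg$eps_m,
                    max_lag_d = cfg$max_lag_d)
    cl <- filter_tenure(db$clusters, min_tenure_d = cfg$min_tenure_d)
    iv <- assign_stages(tr, breeding_poly, wintering_poly)
    if (!"wintering" %in% iv$stage) {
      wf <- wintering_fallback(tr, cl)
      if (!is.null(wf)) iv <- rbind(iv, wf)
      iv <- iv[order(iv$start), , drop = FALSE]
    }
    cl <- annotate_clusters(cl, iv)
    assignments[[bid]] <- db$assignment
    all_intervals[[bid]] <- iv
    all_clusters[[bid]] <- cl
  }
  intervals <- do.call(rbind, c(all_intervals, list(make.row.names = FALSE)))
  clusters <- do.call(rbind, c(all_clusters, list(make.row.names = FALSE)))
  log_msg(nrow(clusters), " residency clusters (tenure > ",
          cfg$min_tenure_d, " d) across ", length(tracks), " birds")

  # home ranges: one shared projection frame per bird x stage
  hr_list <- vector("list", nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    bid <- clusters$bird_id[i]
    tr <- tracks[[bid]]
    members <- tr[assignments[[bid]] == clusters$cluster_id[i] &
                    tr$bird_id == bid, , drop = FALSE]
    if (nrow(members) < 3) next
    peers <- clusters$bird_id == bid & clusters$stage == clusters$stage[i]
    frame <- list(lon0 = mean(clusters$center_lon[peers]),
                  lat0 = mean(clusters$center_lat[peers]))
    hr_list[[i]] <- tryCatch(
      home_range(members, mass = cfg$ud_level, frame = frame),
      error = function(e) NULL)
  }
  clusters$area_km2 <- vapply(hr_list, function(h) {
    if (is.null(h)) NA_real_ else h$area_km2
  }, numeric(1))

  fidelity <- fidelity_records(clusters, hr_list)
  models <- list(
    overlap_zib = tryCatch(fit_zib_mixed(fidelity), error = function(e) {
      log_msg("overlap ZIB model not fitted: ", conditionMessage(e)); NULL
    }),
    distance_gaussian = tryCatch(fit_gaussian_mixed(fidelity), error = function(e) {
      log_msg("distance model not fitted: ", conditionMessage(e)); NULL
    }))

  # migration routes per bird-year-direction
  bounds <- do.call(rbind, c(lapply(all_clusters, migration_bounds),
                             list(make.row.names = FALSE)))
  itracks <- list()
  if (!is.null(bounds) && nrow(bounds) > 0) {
    for (i in seq_len(nrow(bounds))) {
      bid <- bounds$bird_id[i]
      tr <- tracks[[bid]]
      coll <- collapse_to_centers(tr, assignments[[bid]], all_clusters[[bid]])
      seg <- coll[coll$timestamp >= bounds$start[i] &
                    coll$timestamp <= bounds$end[i], , drop = FALSE]
      if (nrow(seg) < 2) next
      it <- tryCatch(
        interpolate_track(seg, dt_min = cfg$dt_min, method = cfg$interp_method),
        error = function(e) NULL)
      if (is.null(it)) next
      itracks[[length(itracks) + 1]] <- list(
        bird_id = bid, direction = bounds$direction[i],
        cycle_year = bounds$cycle_year[i], track = it)
    }
  }
  log_msg(length(itracks), " interpolated migration tracks")

  routes <- list(); band_obs <- empty_band_obs(); profiles <- list()
  for (dir in c("south", "north")) {
    sel <- Filter(function(x) x$direction == dir, itracks)
    if (length(sel) == 0) next
    mr <- mean_route(lapply(sel, `[[`, "track"), n = cfg$n_route_points,
                     direction = dir)
    routes[[dir]] <- mr
    for (x in sel) {
      band_obs <- rbind(band_obs,
                        band_entry_dates(x$track, x$cycle_year, dir),
                        band_lon_deviation(x$track, mr, x$cycle_year, dir))
    }
    for (kind in c("entry_date", "lon_deviation")) {
      profiles[[paste(dir, kind, sep = "_")]] <- band_repeatability_profile(
        band_obs, kind = kind, direction = dir,
        n_boot = cfg$n_boot, seed = cfg$seed)
    }
  }

  events <- event_table(intervals, clusters)
  event_rpt <- event_repeatability(events, n_boot = cfg$n_boot, seed = cfg$seed)

  summary_tbl <- stage_summary(clusters, fidelity)
  out <- list(config = cfg, filter = flt, intervals = intervals,
              clusters = clusters, home_ranges = hr_list, fidelity = fidelity,
              models = models, bounds = bounds, itracks = itracks,
              routes = routes, band_obs = band_obs, profiles = profiles,
              events = events, event_rpt = event_rpt, summary = summary_tbl)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

#' Per-stage residency and fidelity summary
#'
#' Counts of individuals and residency areas, mean areas per individual
#' and year, mean fixes per area, median home-range size, and the
#' between-year overlap incidence, by annual stage.
#'
#' @param clusters Annotated cluster table with `area_km2`.
#' @param fidelity Fidelity records.
#' @return Data.frame, one row per stage.
#' @export
stage_summary <- function(clusters, fidelity) {
  stages <- c("breeding", "south_migration", "wintering", "north_migration")
  rows <- lapply(stages, function(st) {
    cl <- clusters[clusters$stage == st, , drop = FALSE]
    fd <- fidelity[fidelity$stage == st, , drop = FALSE]
    per_by <- if (nrow(cl) > 0) {
      as.numeric(table(paste(cl$bird_id, cl$cycle_year)))
    } else numeric(0)
    data.frame(
      stage = st,
      n_individuals = length(unique(cl$bird_id)),
      n_residency_areas = nrow(cl),
      mean_areas_per_bird_year = if (length(per_by)) mean(per_by) else NA_real_,
      mean_fixes_per_area = if (nrow(cl)) mean(cl$n_fixes) else NA_real_,
      median_home_range_km2 = stats::median(cl$area_km2, na.rm = TRUE),
      n_year_pairs = nrow(fd),
      overlap_incidence = if (nrow(fd)) mean(fd$any_overlap) else NA_real_,
      mean_overlap_prop = if (nrow(fd)) mean(fd$overlap_prop) else NA_real_,
      mean_min_center_dist_km = if (nrow(fd)) mean(fd$min_center_dist_km) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x) > 0) {
      utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wcsv(res$intervals, "stage_intervals.csv")
  wcsv(res$clusters, "clusters.csv")
  wcsv(res$fidelity, "fidelity_records.csv")
  wcsv(res$band_obs, "band_observations.csv")
  wcsv(res$events, "events.csv")
  wcsv(res$event_rpt, "event_repeatability.csv")
  wcsv(res$summary, "stage_summary.csv")
  for (nm in names(res$profiles)) {
    wcsv(res$profiles[[nm]], paste0("profile_", nm, ".csv"))
  }
  for (nm in names(res$routes)) {
    utils::write.csv(res$routes[[nm]]$points,
                     file.path(out_dir, paste0("mean_route_", nm, ".csv")),
                     row.names = FALSE)
    write_geojson_linestring(res$routes[[nm]]$points,
                             file.path(out_dir, paste0("mean_route_", nm, ".geojson")))
  }
  invisible(out_dir)
}

#' Write a lon/lat point sequence as a GeoJSON LineString
#'
#' @param points Data.frame or matrix with lon, lat columns.
#' @param path Output file.
#' @export
write_geojson_linestring <- function(points, path) {
  gj <- list(type = "Feature", properties = list(),
             geometry = list(type = "LineString",
                             coordinates = unname(as.matrix(points))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Write range polygons as a GeoJSON FeatureCollection
#'
#' @param polys Named list of polygon vertex matrices (lon, lat).
#' @param path Output file.
#' @export
write_geojson_polygons <- function(polys, path) {
  feat <- lapply(names(polys), function(nm) {
    ring <- as.matrix(polys[[nm]])
    ring <- rbind(ring, ring[1, ])   # close the ring
    list(type = "Feature", properties = list(role = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(ring))))
  })
  gj <- list(type = "FeatureCollection", features = feat)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
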