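# Reading/writing Argos fix tables and the ground-speed filter.
#
# A fix table is a data.frame with columns:
#   bird_id (character), timestamp (POSIXct, UTC), lon, lat (degrees WGS84),
#   lc (location class, one of "3","2","1","0","A","B"), error_radius_m
#   (numeric, NA when Argos supplies none).
# A track is the time-ordered fix table of a single bird.

.FIX_COLS <- c("bird_id", "timestamp", "lon", "lat", "lc", "error_radius_m")
.ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B")

#' Read a telemetry fix table from CSV
#'
#' Expects columns `bird_id, timestamp, lon, lat, lc, error_radius_m`
#' (ISO-8601 UTC timestamps). Rows with unparseable coordinates or timestamps
#' are dropped with a warning giving the count.
#'
#' @param path CSV file path.
#' @return Fix table sorted by bird and time.
#' @export
read_fixes <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(.FIX_COLS, names(raw))
  if (length(missing) > 0) {
    stop("fix table is missing required columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(empty_fixes())
  }
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d"))
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad <- is.na(ts) | is.na(lon) | is.na(lat) | lat < -90 | lat > 90 |
    lon < -180 | lon > 180
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable or out-of-range values skipped")
  }
  fx <- data.frame(
    bird_id = raw$bird_id[!bad],
    timestamp = ts[!bad],
    lon = lon[!bad],
    lat = lat[!bad],
    lc = raw$lc[!bad],
    error_radius_m = suppressWarnings(as.numeric(raw$error_radius_m[!bad])),
    stringsAsFactors = FALSE
  )
  fx[order(fx$bird_id, fx$timestamp), , drop = FALSE]
}

#' Write a fix table to CSV
#'
#' Timestamps are written as ISO-8601 UTC so that a write/read round trip is
#' lossless to the second.
#'
#' @param fixes Fix table.
#' @param path Output path.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out[, .FIX_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

empty_fixes <- function() {
  data.frame(bird_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
             lon = numeric(), lat = numeric(), lc = character(),
             error_radius_m = numeric(), stringsAsFactors = FALSE)
}

#' Split a fix table into per-bird tracks
#'
#' @param fixes Fix table.
#' @return Named list of time-ordered single-bird fix tables.
#' @export
split_tracks <- function(fixes) {
  fixes <- fixes[order(fixes$bird_id, fixes$timestamp), , drop = FALSE]
  split(fixes, fixes$bird_id)
}

#' Drop fixes named in an exclusion list
#'
#' Real-data workflows often remove a handful of visually identified
#' erroneous locations; an exclusion list (CSV with columns `bird_id`,
#' `timestamp`) makes those removals reproducible.
#'
#' @param fixes Fix table.
#' @param path CSV exclusion list.
#' @return Fix table without the listed fixes; the number removed is
#'   reported in a message.
#' @export
apply_exclusions <- function(fixes, path) {
  ex <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bird_id", "timestamp") %in% names(ex)))
  ex_t <- as.POSIXct(ex$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  key <- paste(fixes$bird_id, as.numeric(fixes$timestamp))
  drop <- key %in% paste(ex$bird_id, as.numeric(ex_t))
  message(sum(drop), " fix(es) removed by exclusion list")
  fixes[!drop, , drop = FALSE]
}

#' Ground speed between two fixes
#'
#' Geodesic distance over elapsed time, in km/h. Errors on non-positive
#' elapsed time (duplicate timestamps must be resolved upstream).
#'
#' @param lon1,lat1,t1 First fix coordinates and POSIXct time.
#' @param lon2,lat2,t2 Second fix; `t2 > t1`.
#' @param method Distance method, see [geo_dist_m()].
#' @return Speed(s) in km/h.
#' @export
ground_speed <- function(lon1, lat1, t1, lon2, lat2, t2,
                         method = c("ellipsoid", "haversine")) {
  dt_h <- as.numeric(difftime(t2, t1, units = "hours"))
  if (any(dt_h <= 0)) {
    stop("non-increasing timestamps: ground speed requires t2 > t1 ",
         "(duplicate timestamps?)")
  }
  geo_dist_m(lon1, lat1, lon2, lat2, method = match.arg(method)) / 1000 / dt_h
}

#' Filter a track by maximum plausible ground speed
#'
#' Iterative forward pass: walking through the track in time order, a fix
#' whose speed from the last kept fix exceeds `vmax_kmh` is dropped, and the
#' next fix is tested against the same kept fix. The first fix is never
#' removed. The result is idempotent and every speed between consecutive kept
#' fixes is at most `vmax_kmh`.
#'
#' @param track Single-bird fix table, time-ordered, no duplicate timestamps.
#' @param vmax_kmh Speed threshold in km/h (default 150).
#' @param method Distance method, see [geo_dist_m()].
#' @return List with `kept` (filtered track) and `removed` (dropped fixes).
#' @export
speed_filter <- function(track, vmax_kmh = 150, method = c("ellipsoid", "haversine")) {
  method <- match.arg(method)
  n <- nrow(track)
  if (n <= 1) {
    return(list(kept = track, removed = track[0, , drop = FALSE]))
  }
  keep <- logical(n)
  keep[1] <- TRUE
  anchor <- 1
  for (i in 2:n) {
    v <- ground_speed(track$lon[anchor], track$lat[anchor], track$timestamp[anchor],
                      track$lon[i], track$lat[i], track$timestamp[i], method = method)
    if (v <= vmax_kmh) {
      keep[i] <- TRUE
      anchor <- i
    }
  }
  list(kept = track[keep, , drop = FALSE],
       removed = track[!keep, , drop = FALSE])
}

#' Apply the speed filter to a multi-bird fix table
#'
#' @param fixes Fix table.
#' @param vmax_kmh Speed threshold in km/h.
#' @param method Distance method.
#' @return List with `kept`, `removed` and `removed_fraction`.
#' @export
filter_fixes <- function(fixes, vmax_kmh = 150, method = c("ellipsoid", "haversine")) {
  method <- match.arg(method)
  res <- lapply(split_tracks(fixes), speed_filter, vmax_kmh = vmax_kmh, method = method)
  kept <- do.call(rbind, c(lapply(res, `[[`, "kept"), list(make.row.names = FALSE)))
  removed <- do.call(rbind, c(lapply(res, `[[`, "removed"), list(make.row.names = FALSE)))
  if (is.null(kept)) kept <- empty_fixes()
  if (is.null(removed)) removed <- empty_fixes()
  list(kept = kept, removed = removed,
       removed_fraction = if (nrow(fixes) > 0) nrow(removed) / nrow(fixes) else 0)
}
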