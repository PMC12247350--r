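# Annual-stage segmentation: breeding / southward migration / wintering /
# northward migration, from range polygons plus cluster-based special cases.

.STAGES <- c("breeding", "south_migration", "wintering", "north_migration")

#' Assign annual stages to a track from range polygons
#'
#' A breeding (wintering) season runs from the first fix inside the breeding
#' (wintering) range to the last fix inside it before the bird next appears
#' in the other range; boundary fixes count as inside (closed polygons).
#' Migration intervals fill the gaps, directed by the order of the flanking
#' seasons (breeding -> wintering = southward). Fixes before the first and
#' after the last season are assigned to a migration heading toward /
#' away from it. Each interval carries a cycle-year label: the calendar year
#' in which the interval starts.
#'
#' Opening or closing a season requires a run of at least `min_run`
#' consecutive in-range fixes, so a single gross location error that lands
#' inside a range cannot create or split a season (an automated stand-in
#' for manual screening of clearly erroneous locations).
#'
#' @param track Single-bird fix table, filtered and time-ordered.
#' @param breeding_poly,wintering_poly Polygon vertex matrices (lon, lat).
#' @param min_run Minimum consecutive in-range fixes for a season (default 2).
#' @return Data.frame of stage intervals: bird_id, stage, start, end,
#'   cycle_year; ordered, non-overlapping. If the track never enters either
#'   range, a single migration interval is returned with a warning.
#' @export
assign_stages <- function(track, breeding_poly, wintering_poly, min_run = 2) {
  n <- nrow(track)
  stopifnot(n >= 1)
  lab <- rep("M", n)
  lab[point_in_polygon(track$lon, track$lat, breeding_poly)] <- "B"
  lab[point_in_polygon(track$lon, track$lat, wintering_poly)] <- "W"
  # discard in-range runs shorter than min_run (isolated erroneous fixes);
  # repeat until stable since removals can merge flanking runs
  repeat {
    r <- rle(lab)
    short <- r$values != "M" & r$lengths < min_run
    if (!any(short)) break
    ends <- cumsum(r$lengths)
    for (k in which(short)) {
      lab[(ends[k] - r$lengths[k] + 1):ends[k]] <- "M"
    }
  }
  in_rng <- which(lab != "M")
  if (length(in_rng) == 0) {
    warning("track for bird ", track$bird_id[1],
            " never enters either range; returning migration-only segmentation")
    dir <- if (track$lat[n] <= track$lat[1]) "south_migration" else "north_migration"
    return(data.frame(bird_id = track$bird_id[1], stage = dir,
                      start = track$timestamp[1], end = track$timestamp[n],
                      cycle_year = year_of(track$timestamp[1]),
                      stringsAsFactors = FALSE))
  }
  # collapse the B/W subsequence into season blocks
  rl <- rle(lab[in_rng])
  ends <- cumsum(rl$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  seasons <- data.frame(
    stage = ifelse(rl$values == "B", "breeding", "wintering"),
    start = track$timestamp[in_rng[starts]],
    end = track$timestamp[in_rng[ends]])
  iv <- list()
  add <- function(stage, start, end) {
    iv[[length(iv) + 1]] <<- data.frame(
      bird_id = track$bird_id[1], stage = stage, start = start, end = end,
      cycle_year = year_of(start), stringsAsFactors = FALSE)
  }
  mig_dir <- function(from_stage, to_stage) {
    if (identical(from_stage, "breeding") || identical(to_stage, "wintering"))
      "south_migration" else "north_migration"
  }
  # leading fixes before the first season
  if (track$timestamp[1] < seasons$start[1]) {
    pre <- track$timestamp[track$timestamp < seasons$start[1]]
    add(mig_dir(NULL, seasons$stage[1]), min(pre), max(pre))
  }
  for (k in seq_len(nrow(seasons))) {
    add(seasons$stage[k], seasons$start[k], seasons$end[k])
    if (k < nrow(seasons)) {
      gap <- track$timestamp[track$timestamp > seasons$end[k] &
                               track$timestamp < seasons$start[k + 1]]
      gs <- if (length(gap) > 0) min(gap) else seasons$end[k] + 1
      ge <- if (length(gap) > 0) max(gap) else seasons$start[k + 1] - 1
      add(mig_dir(seasons$stage[k], seasons$stage[k + 1]), gs, ge)
    }
  }
  if (track$timestamp[n] > seasons$end[nrow(seasons)]) {
    post <- track$timestamp[track$timestamp > seasons$end[nrow(seasons)]]
    add(mig_dir(seasons$stage[nrow(seasons)], NULL), min(post), max(post))
  }
  do.call(rbind, c(iv, list(make.row.names = FALSE)))
}

year_of <- function(t) as.integer(format(t, "%Y", tz = "UTC"))

#' Stage label for every fix of a track
#'
#' @param track Single-bird fix table.
#' @param intervals Stage intervals from [assign_stages()].
#' @return Character vector of stages, one per fix.
#' @export
stage_of_fixes <- function(track, intervals) {
  out <- rep(NA_character_, nrow(track))
  for (k in seq_len(nrow(intervals))) {
    inside <- track$timestamp >= intervals$start[k] &
      track$timestamp <= intervals$end[k]
    out[inside & is.na(out)] <- intervals$stage[k]
  }
  # fixes falling between interval endpoints (empty gaps) join the next interval
  for (i in which(is.na(out))) {
    k <- which(intervals$start >= track$timestamp[i])[1]
    if (is.na(k)) k <- nrow(intervals)
    out[i] <- intervals$stage[k]
  }
  out
}

#' Annotate residency clusters with stage and cycle year
#'
#' Each cluster takes the stage of the interval containing its temporal
#' midpoint and that interval's cycle-year label.
#'
#' @param clusters Cluster summary table for one bird.
#' @param intervals Stage intervals for the same bird.
#' @return Cluster table with `stage` and `cycle_year` columns.
#' @export
annotate_clusters <- function(clusters, intervals) {
  if (nrow(clusters) == 0) {
    clusters$stage <- character(0)
    clusters$cycle_year <- integer(0)
    return(clusters)
  }
  mid <- clusters$start + (clusters$end - clusters$start) / 2
  stage <- rep(NA_character_, nrow(clusters))
  cyear <- rep(NA_integer_, nrow(clusters))
  for (k in seq_len(nrow(intervals))) {
    hit <- mid >= intervals$start[k] & mid <= intervals$end[k] & is.na(stage)
    stage[hit] <- intervals$stage[k]
    cyear[hit] <- intervals$cycle_year[k]
  }
  miss <- is.na(stage)
  if (any(miss)) {
    for (i in which(miss)) {
      k <- which.min(abs(as.numeric(difftime(intervals$start, mid[i], units = "secs"))))
      stage[i] <- intervals$stage[k]
      cyear[i] <- intervals$cycle_year[k]
    }
  }
  clusters$stage <- stage
  clusters$cycle_year <- cyear
  clusters
}

#' Onset of a sustained northward flight
#'
#' First fix after `after` from which the bird moves at least `d_north_km`
#' poleward within `window_h` hours; used to close a wintering season for
#' birds wintering outside the known range.
#'
#' @param track Single-bird fix table.
#' @param after POSIXct; only fixes after this time are considered.
#' @param d_north_km Displacement threshold (km), default 100.
#' @param window_h Time window (hours), default 24.
#' @return POSIXct time of the onset fix, or NA if none.
#' @export
northward_onset <- function(track, after, d_north_km = 100, window_h = 24) {
  idx <- which(track$timestamp > after)
  for (i in idx) {
    w <- which(track$timestamp > track$timestamp[i] &
                 track$timestamp <= track$timestamp[i] + window_h * 3600)
    if (length(w) == 0) next
    if (max((track$lat[w] - track$lat[i])) * 111.195 >= d_north_km) {
      return(track$timestamp[i])
    }
  }
  as.POSIXct(NA, tz = "UTC")
}

#' Wintering season for a bird that never enters the wintering range
#'
#' The wintering season starts at the first residency cluster (tenure > 1 d)
#' overlapping the configured wintering calendar window and ends at the
#' onset of the first sustained northward flight after that (or at the end
#' of the last qualifying cluster when no such flight is found).
#'
#' @param track Single-bird fix table.
#' @param clusters Cluster summary table for the bird (tenure-filtered).
#' @param window_start,window_end Month-day strings delimiting the typical
#'   wintering period, defaults "11-01" and "03-01" (spanning 1 January).
#' @param d_north_km Northward-onset threshold, see [northward_onset()].
#' @return One-row stage-interval data.frame, or NULL (with a message) when
#'   no residency cluster qualifies.
#' @export
wintering_fallback <- function(track, clusters, window_start = "11-01",
                               window_end = "03-01", d_north_km = 100) {
  if (nrow(clusters) == 0) {
    message("bird ", track$bird_id[1], ": no residency clusters; ",
            "excluded from wintering analyses")
    return(NULL)
  }
  # a cluster qualifies when its tenure interval overlaps any yearly
  # occurrence of the wintering window
  spans_window <- function(s, e) {
    for (y in (year_of(s) - 1):(year_of(e) + 1)) {
      ws <- as.POSIXct(paste0(y, "-", window_start), tz = "UTC")
      we <- as.POSIXct(paste0(y + (window_start > window_end), "-", window_end),
                       tz = "UTC")
      if (s <= we && e >= ws) return(TRUE)
    }
    FALSE
  }
  hit <- vapply(seq_len(nrow(clusters)), function(i) {
    spans_window(clusters$start[i], clusters$end[i])
  }, logical(1))
  qual <- clusters[hit, , drop = FALSE]
  if (nrow(qual) == 0) {
    message("bird ", track$bird_id[1], ": no residency cluster within the ",
            "wintering window; excluded from wintering analyses")
    return(NULL)
  }
  qual <- qual[order(qual$start), , drop = FALSE]
  w_start <- qual$start[1]
  w_end <- northward_onset(track, after = w_start, d_north_km = d_north_km)
  if (is.na(w_end)) w_end <- max(qual$end)
  data.frame(bird_id = track$bird_id[1], stage = "wintering",
             start = w_start, end = w_end,
             cycle_year = year_of(w_start), stringsAsFactors = FALSE)
}

#' Migration start and end anchored on longest-tenure residency sites
#'
#' A southward migration in cycle year y runs from the last date at the
#' longest-tenure breeding cluster of year y to the first date at the
#' longest-tenure wintering cluster of year y; a northward migration in
#' year y runs from the last date at the longest-tenure wintering cluster
#' of year y - 1 to the first date at the longest-tenure breeding cluster
#' of year y. Tenure ties are broken by larger fix count, then earlier
#' start. Bird-years missing an anchor on either end are skipped.
#'
#' @param clusters Annotated cluster table (one bird), with `stage` and
#'   `cycle_year` from [annotate_clusters()].
#' @return Data.frame: bird_id, direction ("south"/"north"), cycle_year,
#'   start, end.
#' @export
migration_bounds <- function(clusters) {
  anchor <- function(stage, year) {
    cand <- clusters[clusters$stage == stage & clusters$cycle_year == year, ,
                     drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand <- cand[order(-cand$tenure_d, -cand$n_fixes, cand$start), , drop = FALSE]
    cand[1, , drop = FALSE]
  }
  out <- list()
  years <- sort(unique(clusters$cycle_year))
  for (y in years) {
    ba <- anchor("breeding", y)
    wa <- anchor("wintering", y)
    if (!is.null(ba) && !is.null(wa) && wa$start > ba$end) {
      out[[length(out) + 1]] <- data.frame(
        bird_id = clusters$bird_id[1], direction = "south", cycle_year = y,
        start = ba$end, end = wa$start, stringsAsFactors = FALSE)
    }
    wp <- anchor("wintering", y - 1)
    if (!is.null(wp) && !is.null(ba) && ba$start > wp$end) {
      out[[length(out) + 1]] <- data.frame(
        bird_id = clusters$bird_id[1], direction = "north", cycle_year = y,
        start = wp$end, end = ba$start, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(bird_id = character(), direction = character(),
                      cycle_year = integer(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Annual-event dates per bird and cycle year
#'
#' Extracts the seven timed events analysed for repeatability: arrival at
#' and departure from the breeding and wintering ranges, and the start,
#' end and duration of south-bound stopover (first stopover start to last
#' stopover end during southward migration). Values are fractional days of
#' year (duration in days).
#'
#' @param intervals Stage intervals (any number of birds).
#' @param clusters Annotated cluster table (same birds).
#' @return Data.frame: bird_id, cycle_year, event, value.
#' @export
event_table <- function(intervals, clusters) {
  doy <- function(t) {
    as.numeric(difftime(t, as.POSIXct(paste0(format(t, "%Y", tz = "UTC"), "-01-01"),
                                      tz = "UTC"), units = "days"))
  }
  rows <- list()
  put <- function(b, y, ev, val) {
    rows[[length(rows) + 1]] <<- data.frame(bird_id = b, cycle_year = y,
                                            event = ev, value = val,
                                            stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(intervals))) {
    b <- intervals$bird_id[k]; y <- intervals$cycle_year[k]
    if (intervals$stage[k] == "breeding") {
      put(b, y, "breeding_arrival", doy(intervals$start[k]))
      put(b, y, "breeding_departure", doy(intervals$end[k]))
    } else if (intervals$stage[k] == "wintering") {
      put(b, y, "wintering_arrival", doy(intervals$start[k]))
      put(b, y + 1, "wintering_departure", doy(intervals$end[k]))
    }
  }
  sc <- clusters[clusters$stage == "south_migration", , drop = FALSE]
  if (nrow(sc) > 0) {
    for (b in unique(sc$bird_id)) {
      for (y in unique(sc$cycle_year[sc$bird_id == b])) {
        s <- sc[sc$bird_id == b & sc$cycle_year == y, , drop = FALSE]
        put(b, y, "south_stopover_start", doy(min(s$start)))
        put(b, y, "south_stopover_end", doy(max(s$end)))
        put(b, y, "south_stopover_duration",
            as.numeric(difftime(max(s$end), min(s$start), units = "days")))
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
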