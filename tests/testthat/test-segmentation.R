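test_that("points on a polygon boundary count as inside", {
  poly <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_true(point_in_polygon(0, 0, poly))     # vertex
  expect_true(point_in_polygon(5, 0, poly))     # edge
  expect_true(point_in_polygon(5, 5, poly))     # interior
  expect_false(point_in_polygon(10.01, 5, poly))
  expect_false(point_in_polygon(-0.01, 0, poly))
})

test_that("a clean annual cycle yields the four ordered stages", {
  sim <- small_sim()
  tr <- split_tracks(sim$sim$fixes)[["bird01"]]
  iv <- assign_stages(tr, sim$cfg$breeding_polygon, sim$cfg$wintering_polygon)
  expect_setequal(unique(iv$stage),
                  c("breeding", "south_migration", "wintering", "north_migration"))
  expect_true(all(diff(as.numeric(iv$start)) > 0))
  # intervals are non-overlapping
  expect_true(all(iv$end[-nrow(iv)] < iv$start[-1]))
  # two simulated years: two breeding seasons and two winters
  expect_equal(sum(iv$stage == "breeding"), 2)
  expect_equal(sum(iv$stage == "wintering"), 2)
})

test_that("every fix receives exactly one stage", {
  sim <- small_sim()
  for (tr in split_tracks(sim$sim$fixes)) {
    iv <- assign_stages(tr, sim$cfg$breeding_polygon, sim$cfg$wintering_polygon)
    st <- stage_of_fixes(tr, iv)
    expect_false(any(is.na(st)))
  }
})

test_that("true breeding residency fixes are labeled breeding", {
  # noise-free generator: stage labels should be recovered exactly for
  # residency fixes
  cfg <- sim_config(n_birds = 2, n_years = 2, seed = 5, fix_interval_h = 8,
                    argos_error_sd_m = c("3" = 0, "2" = 0, "1" = 0,
                                         "0" = 0, "A" = 0, "B" = 0))
  sim <- generate_population(cfg)
  for (tr in split_tracks(sim$fixes)) {
    iv <- assign_stages(tr, cfg$breeding_polygon, cfg$wintering_polygon)
    st <- stage_of_fixes(tr, iv)
    tt <- sim$truth$segments[sim$truth$segments$bird_id == tr$bird_id[1], ]
    res_breed <- tt$type == "residency" & tt$stage == "breeding"
    expect_true(all(st[res_breed] == "breeding"))
    res_wint <- tt$type == "residency" & tt$stage == "wintering"
    expect_true(all(st[res_wint] == "wintering"))
  }
})

test_that("a track never entering either range degrades to migration with a warning", {
  tr <- make_steady_track(10, speed_kmh = 40, lon0 = 0, lat0 = 50)
  poly_b <- cbind(c(10, 11, 11, 10), c(60, 60, 61, 61))
  poly_w <- cbind(c(10, 11, 11, 10), c(10, 10, 11, 11))
  expect_warning(iv <- assign_stages(tr, poly_b, poly_w), "never enters")
  expect_equal(nrow(iv), 1)
  expect_match(iv$stage, "migration")
})

test_that("northward flight onset detector fires at the configured displacement", {
  t0 <- ts_utc("2021-02-01")
  lat <- c(rep(25, 5), 25.3, 26.5, 28, 30)    # > 100 km poleward within 24 h
  tr <- make_track(rep(-100, 9), lat, t0 + (0:8) * 6 * 3600)
  onset <- northward_onset(tr, after = t0 - 1)
  # first fix from which >= 100 km poleward displacement occurs within 24 h:
  # fix 3 (12 h) already sees fix 7 (36 h) at 26.5 deg, ~167 km north
  expect_equal(onset, tr$timestamp[3])
  # stationary track: no onset
  tr2 <- make_track(rep(-100, 5), rep(25, 5), t0 + (0:4) * 6 * 3600)
  expect_true(is.na(northward_onset(tr2, after = t0 - 1)))
})

test_that("wintering fallback recovers a season for birds outside the known range", {
  sim <- small_sim()
  tr <- split_tracks(sim$sim$fixes)[["bird01"]]
  db <- st_dbscan(tr)
  cl <- filter_tenure(db$clusters)
  # shift the wintering polygon far east so the bird never enters it
  wp_shift <- sim$cfg$wintering_polygon
  wp_shift[, 1] <- wp_shift[, 1] + 60
  iv <- assign_stages(tr, sim$cfg$breeding_polygon, wp_shift)
  expect_false("wintering" %in% iv$stage)
  wf <- wintering_fallback(tr, cl)
  expect_equal(wf$stage, "wintering")
  # the recovered season overlaps the bird's true wintering residency
  tt <- sim$sim$truth$segments
  true_w <- tt[tt$bird_id == "bird01" & tt$stage == "wintering" &
                 tt$type == "residency", ]
  expect_lt(as.numeric(difftime(wf$start, min(true_w$timestamp), units = "days")), 20)
  # no residency at all: flagged with a message
  drift <- make_steady_track(30, speed_kmh = 12, step_h = 12)
  dcl <- filter_tenure(st_dbscan(drift)$clusters)
  expect_message(out <- wintering_fallback(drift, dcl), "excluded")
  expect_null(out)
})

test_that("migration bounds anchor on longest-tenure sites with documented tie-breaks", {
  t0 <- ts_utc("2021-06-01")
  mk <- function(id, stage, year, start_d, end_d, n_fixes) {
    data.frame(cluster_id = id, bird_id = "b1",
               start = t0 + start_d * 86400, end = t0 + end_d * 86400,
               tenure_d = end_d - start_d, n_fixes = n_fixes,
               center_lon = -100, center_lat = 30, stage = stage,
               cycle_year = year, stringsAsFactors = FALSE)
  }
  cl <- rbind(mk(1, "breeding", 2021, 0, 30, 50),
              mk(2, "breeding", 2021, 35, 65, 80),   # same tenure, more fixes
              mk(3, "wintering", 2021, 130, 250, 300))
  b <- migration_bounds(cl)
  expect_equal(nrow(b), 1)
  expect_equal(b$direction, "south")
  # tie on tenure broken by the larger fix count: anchor is cluster 2
  expect_equal(b$start, cl$end[2])
  expect_equal(b$end, cl$start[3])
})

test_that("migration bounds bracket the true flight legs on simulated data", {
  sim <- small_sim()
  tt <- sim$sim$truth$segments
  for (tr in split_tracks(sim$sim$fixes)) {
    db <- st_dbscan(tr)
    cl <- filter_tenure(db$clusters)
    iv <- assign_stages(tr, sim$cfg$breeding_polygon, sim$cfg$wintering_polygon)
    cl <- annotate_clusters(cl, iv)
    b <- migration_bounds(cl)
    b <- b[b$direction == "south", , drop = FALSE]
    expect_gt(nrow(b), 0)
    for (i in seq_len(nrow(b))) {
      fly <- tt[tt$bird_id == tr$bird_id[1] & tt$type == "flight" &
                  tt$stage == "south_migration" &
                  as.integer(format(tt$timestamp, "%Y")) == b$cycle_year[i], ]
      if (nrow(fly) == 0) next
      expect_lte(b$start[i], min(fly$timestamp) + 86400)
      expect_gte(b$end[i], max(fly$timestamp) - 86400)
    }
  }
})

test_that("event table extracts the seven timed variables", {
  sim <- small_sim()
  tr <- split_tracks(sim$sim$fixes)[["bird02"]]
  db <- st_dbscan(tr)
  cl <- filter_tenure(db$clusters)
  iv <- assign_stages(tr, sim$cfg$breeding_polygon, sim$cfg$wintering_polygon)
  cl <- annotate_clusters(cl, iv)
  ev <- event_table(iv, cl)
  expect_true(all(c("breeding_arrival", "breeding_departure",
                    "wintering_arrival") %in% ev$event))
  # event dates are plausible days of year
  doy <- ev$value[ev$event != "south_stopover_duration"]
  expect_true(all(doy >= 0 & doy < 366))
  # stopover duration equals end minus start within each bird-year
  for (y in unique(ev$cycle_year[ev$event == "south_stopover_duration"])) {
    sel <- ev$cycle_year == y
    dur <- ev$value[sel & ev$event == "south_stopover_duration"]
    s <- ev$value[sel & ev$event == "south_stopover_start"]
    e <- ev$value[sel & ev$event == "south_stopover_end"]
    if (length(dur) == 1 && length(s) == 1 && length(e) == 1) {
      expect_equal(dur, e - s, tolerance = 1e-8)
    }
  }
})
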