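test_that("collapsing to centers replaces only clustered fixes", {
  t0 <- ts_utc("2021-01-01")
  tr <- make_track(c(-100.01, -100.02, -99.99, -95), c(30.01, 29.99, 30.02, 33),
                   t0 + (0:3) * 86400 / 4)
  cl <- data.frame(cluster_id = 1L, bird_id = "b1", start = t0, end = t0 + 3600,
                   tenure_d = 2, n_fixes = 3L, center_lon = -100,
                   center_lat = 30, stringsAsFactors = FALSE)
  out <- collapse_to_centers(tr, c(1L, 1L, 1L, 0L), cl)
  expect_equal(out$lon, c(-100, -100, -100, -95))
  expect_equal(out$lat, c(30, 30, 30, 33))
  expect_equal(out$timestamp, tr$timestamp)
  # no clusters: unchanged
  expect_equal(collapse_to_centers(tr, rep(0L, 4), cl[0, ]), tr)
})

test_that("linear interpolation passes through great-circle midpoints", {
  t0 <- ts_utc("2021-09-01")
  tr <- make_track(c(-150, -100), c(65, 35), c(t0, t0 + 10 * 3600))
  it <- interpolate_track(tr, dt_min = 30, method = "linear")
  mid <- it[it$timestamp == t0 + 5 * 3600, ]
  # independent spherical great-circle oracle
  want <- geosphere::gcIntermediate(c(-150, 65), c(-100, 35), n = 1)
  expect_equal(unname(mid$lon), unname(want[1, "lon"]), tolerance = 1e-6)
  expect_equal(unname(mid$lat), unname(want[1, "lat"]), tolerance = 1e-6)
})

test_that("stationary tracks interpolate to the fixed point", {
  t0 <- ts_utc("2021-09-01")
  tr <- make_track(rep(-100, 10), rep(35, 10), t0 + (0:9) * 6 * 3600)
  for (m in c("linear", "crw")) {
    it <- interpolate_track(tr, method = m)
    expect_lt(max(geosphere::distGeo(cbind(it$lon, it$lat), c(-100, 35))), 500)
  }
})

test_that("positions inside a 3-day transmission gap are flagged invalid", {
  t0 <- ts_utc("2021-09-01")
  times <- c(t0 + (0:5) * 6 * 3600, t0 + 4 * 86400 + (0:5) * 6 * 3600)
  tr <- make_track(rep(-100, 12), seq(40, 35, length.out = 12), times)
  it <- interpolate_track(tr, method = "linear")
  gap_mid <- it$timestamp > t0 + 2 * 86400 & it$timestamp < t0 + 3 * 86400
  expect_true(all(!it$valid[gap_mid]))
  expect_true(all(it$valid[it$timestamp <= t0 + 12 * 3600]))
})

test_that("validity flags depend only on fix timestamps, not coordinates", {
  t0 <- ts_utc("2021-09-01")
  times <- c(t0 + (0:3) * 6 * 3600, t0 + 3 * 86400 + (0:3) * 6 * 3600)
  tr1 <- make_track(rep(-100, 8), seq(40, 36, length.out = 8), times)
  tr2 <- tr1
  tr2$lon <- tr2$lon + rnorm(8)
  v1 <- interpolate_track(tr1, method = "linear")$valid
  v2 <- interpolate_track(tr2, method = "linear")$valid
  expect_identical(v1, v2)
})

test_that("the CRW smoother tracks dense low-noise fixes closely", {
  t0 <- ts_utc("2021-09-01")
  n <- 40
  tr <- make_track(seq(-150, -140, length.out = n),
                   seq(65, 55, length.out = n),
                   t0 + (0:(n - 1)) * 3600, lc = "3")
  it <- interpolate_track(tr, method = "crw",
                          obs_sd_m = c("3" = 1, "2" = 1, "1" = 1,
                                       "0" = 1, "A" = 1, "B" = 1))
  at_fix <- it[it$timestamp %in% tr$timestamp, ]
  d <- geosphere::distGeo(cbind(at_fix$lon, at_fix$lat),
                          cbind(tr$lon, tr$lat))
  expect_lt(max(d), 2000)
})

test_that("a single track's mean route is the track itself resampled", {
  t0 <- ts_utc("2021-09-01")
  n <- 100
  tr <- make_track(seq(-150, -100, length.out = n),
                   seq(65, 25, length.out = n), t0 + (0:(n - 1)) * 6 * 3600)
  tr$valid <- TRUE
  mr <- mean_route(list(tr), n = n, direction = "south", thin_m = 0)
  rs <- trackfidelity:::resample_route(tr$lon, tr$lat, n)
  expect_equal(mr$points$lon, rs[, "lon"], tolerance = 1e-9)
  expect_equal(mr$points$lat, rs[, "lat"], tolerance = 1e-9)
  # the residual objective is exactly the resampling granularity: the mean
  # distance from resampled points to the nearest original vertex
  vx <- trackfidelity:::lonlat_to_xyz(tr$lon, tr$lat)
  qx <- trackfidelity:::lonlat_to_xyz(rs[, "lon"], rs[, "lat"])
  nv <- trackfidelity:::nearest_vertex(vx, qx)
  want <- mean(geosphere::distGeo(rs, cbind(tr$lon, tr$lat)[nv, ])) / 1000
  expect_equal(utils::tail(mr$objective_km, 1), want, tolerance = 1e-9)
})

test_that("two symmetric meridian tracks average to the midline", {
  t0 <- ts_utc("2021-09-01")
  mk <- function(lon) {
    tr <- make_track(rep(lon, 60), seq(50, 30, length.out = 60),
                     t0 + (0:59) * 6 * 3600)
    tr$valid <- TRUE
    tr
  }
  mr <- mean_route(list(mk(-1), mk(1)), n = 200, direction = "south")
  expect_true(all(abs(mr$points$lon) < 1 / 111))   # within ~1 km of lon 0
  expect_true(all(diff(mr$points$lat) <= 1e-9))    # monotone southward
})

test_that("the mean-route objective is non-increasing and translation-equivariant", {
  set.seed(4)
  t0 <- ts_utc("2021-09-01")
  mk <- function(lon_off) {
    n <- 80
    tr <- make_track(-100 + lon_off + cumsum(rnorm(n, 0, 0.15)),
                     seq(55, 25, length.out = n), t0 + (0:(n - 1)) * 4 * 3600)
    tr$valid <- TRUE
    tr
  }
  tracks <- lapply(c(-2, -0.5, 1, 2.5), mk)
  mr <- mean_route(tracks, n = 150, direction = "south")
  expect_true(all(diff(mr$objective_km) <= 1e-9))
  shifted <- lapply(tracks, function(tr) { tr$lon <- tr$lon + 10; tr })
  mr2 <- mean_route(shifted, n = 150, direction = "south")
  expect_equal(mr2$points$lon, mr$points$lon + 10, tolerance = 0.02)
  expect_equal(mr2$points$lat, mr$points$lat, tolerance = 0.02)
})

test_that("band entry dates record the first crossing only", {
  t0 <- ts_utc("2021-09-01 00:00:00")
  n <- 97
  lat <- seq(44.9, 38.9, length.out = n)   # steady southward, 0.0625 deg/step
  it <- data.frame(bird_id = "b1", timestamp = t0 + (0:(n - 1)) * 900,
                   lon = -100, lat = lat, valid = TRUE,
                   stringsAsFactors = FALSE)
  obs <- band_entry_dates(it, cycle_year = 2021, direction = "south")
  expect_setequal(obs$band_low_lat, 38:44)
  # first position with lat < 44 is the first in band [43, 44)
  i44 <- which(lat < 44)[1]
  want_doy <- as.numeric(difftime(it$timestamp[i44], ts_utc("2021-01-01"),
                                  units = "days"))
  expect_equal(obs$value[obs$band_low_lat == 43], want_doy)
  # wandering back north and south again does not add entries
  it2 <- it
  it2$lat <- c(lat[1:50], rev(lat[30:50]), lat[30:55])
  obs2 <- band_entry_dates(it2, 2021, "south")
  expect_equal(sum(obs2$band_low_lat == floor(min(it2$lat[1:50]))), 1)
  # track confined to one band gives one observation
  it3 <- it[1:5, ]
  expect_equal(nrow(band_entry_dates(it3, 2021, "south")), 1)
})

test_that("longitudinal deviations are signed east-west geodesic distances", {
  t0 <- ts_utc("2021-09-01")
  n <- 60
  base <- data.frame(bird_id = "b1", timestamp = t0 + (0:(n - 1)) * 900,
                     lon = -100, lat = seq(50, 40, length.out = n),
                     valid = TRUE, stringsAsFactors = FALSE)
  mr <- mean_route(list(base), n = 100, direction = "south", thin_m = 0)
  # identical track: zero deviation everywhere
  d0 <- band_lon_deviation(base, mr, 2021, "south")
  expect_true(all(abs(d0$value) < 1e-6))
  # track shifted 1 degree east at ~45N: ~ +78.6 km
  east <- base; east$lon <- east$lon + 1
  de <- band_lon_deviation(east, mr, 2021, "south")
  want <- geosphere::distGeo(c(-100, 45), c(-99, 45)) / 1000
  expect_equal(de$value[de$band_low_lat == 45], want, tolerance = 0.01)
  expect_true(all(de$value > 0))
  # mirror image: same magnitude, opposite sign
  west <- base; west$lon <- west$lon - 1
  dw <- band_lon_deviation(west, mr, 2021, "south")
  expect_equal(dw$value, -de$value, tolerance = 0.02)
})
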