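# Kernel utilization distributions and between-year fidelity metrics.
#
# Each cluster's UD is fitted on a local azimuthal equal-area projection; the
# 90% home range is the highest-density region: the smallest set of grid
# cells whose probability mass reaches 0.90.

#' Kernel utilization distribution for a residency cluster
#'
#' Bivariate Gaussian kernel density (product kernel, ad-hoc reference
#' bandwidth per axis, h = sd * n^(-1/6)) on a square grid in a local
#' equal-area projection. Clusters with fewer than five fixes have their
#' points cycled (1,2,3,1,2 for a 3-point cluster) up to five before
#' fitting, since a density estimate on 3-4 points is otherwise degenerate.
#' All-identical points get a minimum-bandwidth floor with a warning.
#'
#' @param members Fix table of cluster members (>= 3 rows).
#' @param cell_m Grid cell size in meters; default spans the padded extent
#'   with 200 cells on the longer axis.
#' @param frame Optional list(lon0, lat0) fixing the projection center, so
#'   that several clusters share one frame; defaults to the member centroid.
#' @return Object of class `ud`: grid coordinates `xs`, `ys` (cell centers,
#'   meters), probability-mass matrix `p` (sums to 1), `cell_m`, projection
#'   center `lon0`, `lat0`, bandwidths `h`, and point counts.
#' @export
kde_ud <- function(members, cell_m = NULL, frame = NULL) {
  n_orig <- nrow(members)
  stopifnot(n_orig >= 3)
  if (n_orig < 5) {
    idx <- rep_len(seq_len(n_orig), 5)
    members <- members[idx, , drop = FALSE]
  }
  lon0 <- if (is.null(frame)) mean(members$lon) else frame$lon0
  lat0 <- if (is.null(frame)) mean(members$lat) else frame$lat0
  xy <- laea_project(members$lon, members$lat, lon0, lat0)
  degenerate <- max(apply(xy, 2, function(v) diff(range(v)))) < 1e-6
  if (degenerate) {
    warning("all cluster points identical; applying minimum-bandwidth floor")
  }
  h <- href_bandwidth(xy, floor_m = 100)
  pad <- 3 * h
  ext_x <- range(xy[, 1]) + c(-pad[1], pad[1])
  ext_y <- range(xy[, 2]) + c(-pad[2], pad[2])
  if (is.null(cell_m)) cell_m <- max(diff(ext_x), diff(ext_y)) / 200
  xs <- seq(ext_x[1], ext_x[2], by = cell_m)
  ys <- seq(ext_y[1], ext_y[2], by = cell_m)
  dens <- gauss_kde_grid(xy, xs, ys, h)
  p <- dens / sum(dens)
  structure(list(xs = xs, ys = ys, p = p, cell_m = cell_m,
                 lon0 = lon0, lat0 = lat0, h = h,
                 n_used = nrow(members), n_orig = n_orig),
            class = "ud")
}

#' Highest-density region of a UD at a given mass
#'
#' Grid cells are ranked by density and accumulated until the requested
#' probability mass is reached, giving the smallest region holding that
#' mass; the region is the union of the selected cells. Contained mass lies
#' in [mass, mass + one cell's mass).
#'
#' @param ud A [kde_ud()] surface.
#' @param mass Probability mass, default 0.90.
#' @return List: `cells` (data.frame x, y of covered cell centers, meters),
#'   `area_km2`, `mass_actual`, `cell_m`, `lon0`, `lat0`.
#' @export
contour_at_mass <- function(ud, mass = 0.90) {
  stopifnot(mass > 0, mass <= 1)
  ord <- order(ud$p, decreasing = TRUE)
  cum <- cumsum(ud$p[ord])
  k <- if (mass >= 1) length(ord) else which(cum >= mass - 1e-12)[1]
  sel <- ord[seq_len(k)]
  ij <- arrayInd(sel, dim(ud$p))
  list(cells = data.frame(x = ud$xs[ij[, 1]], y = ud$ys[ij[, 2]]),
       area_km2 = k * ud$cell_m^2 / 1e6,
       mass_actual = cum[k],
       cell_m = ud$cell_m, lon0 = ud$lon0, lat0 = ud$lat0)
}

#' Home range (90% UD) of one residency cluster
#'
#' @param members Cluster member fixes (>= 3).
#' @param mass UD level, default 0.90.
#' @param cell_m Grid cell size (meters); NULL for the 200-cell default.
#' @param frame Optional shared projection frame, see [kde_ud()].
#' @return Object of class `home_range`: the contour cell set, `area_km2`,
#'   the cluster `center` (lon/lat, from [cluster_center()]), and the
#'   projection frame.
#' @export
home_range <- function(members, mass = 0.90, cell_m = NULL, frame = NULL) {
  ud <- kde_ud(members, cell_m = cell_m, frame = frame)
  ctr <- cluster_center(members)
  hr <- contour_at_mass(ud, mass = mass)
  structure(list(cells = hr$cells, cell_m = hr$cell_m,
                 area_km2 = hr$area_km2, mass_actual = hr$mass_actual,
                 center = c(lon = ctr[1], lat = ctr[2]),
                 lon0 = hr$lon0, lat0 = hr$lat0),
            class = "home_range")
}

# Rasterize a home range's cell set onto a common grid (resolution res_m,
# cells aligned to multiples of res_m in the frame lon0/lat0). Returns the
# set of covered common cells as scalar keys i * OFFSET + j.
.RASTER_OFFSET <- 2^26
rasterize_hr <- function(hr, lon0, lat0, res_m) {
  cx <- hr$cells$x
  cy <- hr$cells$y
  if (abs(hr$lon0 - lon0) > 1e-12 || abs(hr$lat0 - lat0) > 1e-12) {
    ll <- laea_unproject(cx, cy, hr$lon0, hr$lat0)
    xy <- laea_project(ll[, "lon"], ll[, "lat"], lon0, lat0)
    cx <- xy[, "x"]; cy <- xy[, "y"]
  }
  half <- hr$cell_m / 2
  # common cells whose centers (i + 0.5) * res fall inside [c - half, c + half)
  i0 <- ceiling((cx - half) / res_m - 0.5 - 1e-9)
  i1 <- floor((cx + half) / res_m - 0.5 - 1e-9)
  j0 <- ceiling((cy - half) / res_m - 0.5 - 1e-9)
  j1 <- floor((cy + half) / res_m - 0.5 - 1e-9)
  out <- vector("list", length(cx))
  for (k in seq_along(cx)) {
    if (i1[k] >= i0[k] && j1[k] >= j0[k]) {
      out[[k]] <- as.vector(outer((i0[k]:i1[k]) * .RASTER_OFFSET,
                                  j0[k]:j1[k], "+"))
    }
  }
  unique(unlist(out))
}

#' Between-year overlap proportion of home ranges
#'
#' Implements the overlap index
#' `2 * area(union(x) intersect union(y)) / (sum of all home-range areas in
#' the two years)`. Identical range sets give 1, disjoint sets give 0; the
#' index is symmetric in its arguments. Intersection areas are computed on a
#' common raster at half the finest home-range cell size.
#'
#' @param hrs_x,hrs_y Lists of `home_range` objects for years x and x + 1.
#' @return List: `overlap_prop`, `any_overlap`, `area_int_km2`.
#' @export
overlap_proportion <- function(hrs_x, hrs_y) {
  if (inherits(hrs_x, "home_range")) hrs_x <- list(hrs_x)
  if (inherits(hrs_y, "home_range")) hrs_y <- list(hrs_y)
  if (length(hrs_x) == 0 || length(hrs_y) == 0) {
    stop("overlap undefined: one year has no home ranges")
  }
  lon0 <- hrs_x[[1]]$lon0; lat0 <- hrs_x[[1]]$lat0
  res_m <- min(vapply(c(hrs_x, hrs_y), function(h) h$cell_m, numeric(1))) / 2
  rast_union <- function(hrs) {
    unique(unlist(lapply(hrs, rasterize_hr, lon0 = lon0, lat0 = lat0,
                         res_m = res_m)))
  }
  kx <- rast_union(hrs_x)
  ky <- rast_union(hrs_y)
  n_int <- sum(kx %in% ky)
  a_int <- n_int * res_m^2 / 1e6
  denom <- sum(vapply(hrs_x, function(h) h$area_km2, numeric(1))) +
    sum(vapply(hrs_y, function(h) h$area_km2, numeric(1)))
  list(overlap_prop = 2 * a_int / denom,
       any_overlap = n_int > 0,
       area_int_km2 = a_int)
}

#' Minimum distance between home-range centers across years
#'
#' @param hrs_x,hrs_y Lists of `home_range` objects.
#' @return Minimum geodesic center-to-center distance in km.
#' @export
min_center_distance <- function(hrs_x, hrs_y) {
  if (inherits(hrs_x, "home_range")) hrs_x <- list(hrs_x)
  if (inherits(hrs_y, "home_range")) hrs_y <- list(hrs_y)
  if (length(hrs_x) == 0 || length(hrs_y) == 0) {
    stop("center distance undefined: one year has no home ranges")
  }
  d <- outer(seq_along(hrs_x), seq_along(hrs_y), Vectorize(function(i, j) {
    geosphere::distGeo(hrs_x[[i]]$center, hrs_y[[j]]$center)
  }))
  min(d) / 1000
}

#' Between-year fidelity records for all bird/stage/year pairs
#'
#' For every bird and stage with home ranges in two consecutive cycle years,
#' computes the overlap proportion and the minimum center distance.
#'
#' @param cluster_table Cluster summary with `stage` and `cycle_year`.
#' @param hr_list List of `home_range` objects parallel to the rows of
#'   `cluster_table`.
#' @return Data.frame: bird_id, stage, year_x, any_overlap, overlap_prop,
#'   min_center_dist_km.
#' @export
fidelity_records <- function(cluster_table, hr_list) {
  stopifnot(nrow(cluster_table) == length(hr_list))
  recs <- list()
  for (b in unique(cluster_table$bird_id)) {
    for (st in unique(cluster_table$stage[cluster_table$bird_id == b])) {
      sel <- which(cluster_table$bird_id == b & cluster_table$stage == st)
      yrs <- sort(unique(cluster_table$cycle_year[sel]))
      for (y in yrs) {
        if (!((y + 1) %in% yrs)) next
        hx <- hr_list[sel[cluster_table$cycle_year[sel] == y]]
        hy <- hr_list[sel[cluster_table$cycle_year[sel] == y + 1]]
        hx <- hx[!vapply(hx, is.null, logical(1))]
        hy <- hy[!vapply(hy, is.null, logical(1))]
        if (length(hx) == 0 || length(hy) == 0) next
        ov <- overlap_proportion(hx, hy)
        recs[[length(recs) + 1]] <- data.frame(
          bird_id = b, stage = st, year_x = y,
          any_overlap = ov$any_overlap, overlap_prop = ov$overlap_prop,
          min_center_dist_km = min_center_distance(hx, hy),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(recs) == 0) {
    return(data.frame(bird_id = character(), stage = character(),
                      year_x = integer(), any_overlap = logical(),
                      overlap_prop = numeric(), min_center_dist_km = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(recs, list(make.row.names = FALSE)))
}
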