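# Residency-area detection: DBSCAN over geodesic distance with a pairwise
# temporal gate (maxLag), so that revisits to the same site after a long
# absence form separate clusters.

#' Spatio-temporal DBSCAN over a track
#'
#' Standard DBSCAN in which two fixes are neighbors only if they lie within
#' `eps_m` (geodesic) of each other AND within `max_lag_d` days of each other.
#' A fix is a core point when its neighborhood (itself included) holds at
#' least `min_pts` fixes. Clusters are the connected components of core
#' points under the neighbor relation; non-core fixes with a core neighbor
#' (border points) are assigned to the cluster of the earliest core point
#' that reaches them, which makes the result independent of expansion order.
#' Remaining fixes are noise.
#'
#' Default parameters `min_pts = 3`, `eps_m = 4000`, `max_lag_d = 10` suit
#' Argos duty cycles of a few fixes per day; a coarser alternative
#' (5 / 8000 m / 20 d) suits birds ranging over larger areas.
#'
#' @param track Single-bird fix table, time-ordered.
#' @param min_pts Minimum neighborhood size to form a core point.
#' @param eps_m Neighborhood radius in meters.
#' @param max_lag_d Temporal gate in days.
#' @return List with `assignment` (integer per fix; 0 = noise, clusters
#'   numbered 1.. in order of first member time), `clusters` (summary
#'   data.frame: cluster_id, bird_id, start, end, tenure_d, n_fixes,
#'   center_lon, center_lat) and `params`.
#' @export
st_dbscan <- function(track, min_pts = 3, eps_m = 4000, max_lag_d = 10) {
  stopifnot(min_pts >= 2, eps_m > 0, max_lag_d > 0)
  n <- nrow(track)
  if (n == 0) {
    return(list(assignment = integer(0),
                clusters = empty_cluster_table(),
                params = list(min_pts = min_pts, eps_m = eps_m, max_lag_d = max_lag_d)))
  }
  t_num <- as.numeric(track$timestamp)
  max_lag_s <- max_lag_d * 86400
  # neighbor lists: temporal window first (cheap), geodesic test second
  los <- findInterval(t_num - max_lag_s - 1e-6, t_num) + 1L
  his <- findInterval(t_num + max_lag_s, t_num)
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- seq.int(los[i], his[i])
    cand <- cand[cand != i]
    if (length(cand) > 0) {
      d <- geosphere::distGeo(cbind(track$lon[i], track$lat[i]),
                              cbind(track$lon[cand], track$lat[cand]))
      nbr[[i]] <- cand[d <= eps_m]
    } else {
      nbr[[i]] <- integer(0)
    }
  }
  core <- vapply(nbr, length, integer(1)) + 1L >= min_pts
  assignment <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {          # time order: ids stable, borders to earliest core
    if (!core[i] || assignment[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    assignment[i] <- cl
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (q in nbr[[p]]) {
        if (assignment[q] == 0L) {
          assignment[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  # border fixes reached by cores from two clusters: reassign to the cluster
  # of the earliest core neighbor (expansion above may have been first-come)
  border <- which(!core & assignment != 0L)
  for (b in border) {
    cn <- nbr[[b]][core[nbr[[b]]] & assignment[nbr[[b]]] != 0L]
    if (length(cn) > 0) assignment[b] <- assignment[min(cn)]
  }
  list(assignment = assignment,
       clusters = summarize_clusters(track, assignment),
       params = list(min_pts = min_pts, eps_m = eps_m, max_lag_d = max_lag_d))
}

empty_cluster_table <- function() {
  data.frame(cluster_id = integer(), bird_id = character(),
             start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"),
             tenure_d = numeric(), n_fixes = integer(),
             center_lon = numeric(), center_lat = numeric(),
             stringsAsFactors = FALSE)
}

summarize_clusters <- function(track, assignment) {
  ids <- sort(unique(assignment[assignment > 0]))
  if (length(ids) == 0) return(empty_cluster_table())
  rows <- lapply(ids, function(k) {
    m <- track[assignment == k, , drop = FALSE]
    ctr <- cluster_center(m)
    data.frame(cluster_id = k, bird_id = m$bird_id[1],
               start = min(m$timestamp), end = max(m$timestamp),
               tenure_d = as.numeric(difftime(max(m$timestamp), min(m$timestamp),
                                              units = "days")),
               n_fixes = nrow(m),
               center_lon = ctr[1], center_lat = ctr[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cluster center as the mode of point density
#'
#' The center is the location of highest smoothed point intensity: a
#' bivariate Gaussian kernel density is evaluated on a grid of spacing
#' `grid_m` over the cluster bounding box (in a local equal-area projection)
#' and the densest grid cell is returned. Ties are broken toward the cell
#' nearest the temporally earliest member fix, so symmetric two-blob
#' clusters resolve to the earlier-occupied blob.
#'
#' @param members Fix table of the cluster members (>= 1 row).
#' @param grid_m Grid spacing in meters.
#' @return Numeric `c(lon, lat)`.
#' @export
cluster_center <- function(members, grid_m = 250) {
  stopifnot(nrow(members) >= 1)
  if (nrow(members) == 1) return(c(members$lon[1], members$lat[1]))
  lon0 <- mean(members$lon); lat0 <- mean(members$lat)
  xy <- laea_project(members$lon, members$lat, lon0, lat0)
  if (max(apply(xy, 2, function(v) diff(range(v)))) < 1e-6) {
    return(c(members$lon[1], members$lat[1]))
  }
  h <- href_bandwidth(xy, floor_m = grid_m)
  xs <- seq(min(xy[, 1]) - h[1], max(xy[, 1]) + h[1], by = grid_m)
  ys <- seq(min(xy[, 2]) - h[2], max(xy[, 2]) + h[2], by = grid_m)
  dens <- gauss_kde_grid(xy, xs, ys, h)
  top <- which(dens >= max(dens) * (1 - 1e-9), arr.ind = TRUE)
  if (nrow(top) > 1) {
    first <- xy[which.min(members$timestamp), ]
    d2 <- (xs[top[, 1]] - first[1])^2 + (ys[top[, 2]] - first[2])^2
    top <- top[which.min(d2), , drop = FALSE]
  }
  ll <- laea_unproject(xs[top[1, 1]], ys[top[1, 2]], lon0, lat0)
  c(ll[1, "lon"], ll[1, "lat"])
}

# Per-axis ad-hoc reference bandwidth for a 2-D Gaussian kernel:
# h_axis = sd_axis * n^(-1/6), floored to keep degenerate clusters finite.
href_bandwidth <- function(xy, floor_m = 50) {
  n <- nrow(xy)
  h <- c(stats::sd(xy[, 1]), stats::sd(xy[, 2])) * n^(-1 / 6)
  h[!is.finite(h) | h < floor_m] <- floor_m
  h
}

# Gaussian product-kernel density on a rectangular grid; returns the
# (length(xs) x length(ys)) matrix of densities (not yet normalized to the
# grid).
gauss_kde_grid <- function(xy, xs, ys, h) {
  gx <- outer(xs, xy[, 1], function(a, b) stats::dnorm(a, b, h[1]))
  gy <- outer(ys, xy[, 2], function(a, b) stats::dnorm(a, b, h[2]))
  (gx %*% t(gy)) / nrow(xy)
}

#' Drop clusters at or below a minimum tenure
#'
#' Residency requires tenure strictly greater than `min_tenure_d` days
#' (a cluster spanning exactly one day is dropped).
#'
#' @param clusters Cluster summary table.
#' @param min_tenure_d Minimum tenure in days (strict).
#' @return Filtered cluster table; attribute `n_dropped` gives the count.
#' @export
filter_tenure <- function(clusters, min_tenure_d = 1) {
  keep <- clusters$tenure_d > min_tenure_d
  out <- clusters[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
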