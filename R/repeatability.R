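# Repeatability (intraclass correlation) from the one-way random-intercept
# model y_ij = mu + a_i + e_ij, a_i ~ N(0, s2_id), e_ij ~ N(0, s2_res):
# R = s2_id / (s2_id + s2_res).
#
# The REML fit is computed by profiling: for a fixed variance ratio
# gamma = s2_id/s2_res the GLS mean and the residual variance have closed
# forms, leaving a 1-D optimization over gamma. This makes the parametric
# bootstrap (thousands of refits of the same tiny model) cheap; the tests
# cross-check the estimates against lme4::lmer and against the balanced
# ANOVA closed form.

# Sufficient statistics per individual.
.group_stats <- function(values, ids) {
  ok <- !is.na(values) & !is.na(ids)
  values <- values[ok]
  f <- factor(ids[ok])
  ni <- tabulate(f)
  s1 <- as.numeric(rowsum(values, f))
  s2 <- as.numeric(rowsum(values^2, f))
  ybar <- s1 / ni
  ssw <- pmax(0, s2 - s1^2 / ni)
  list(ni = ni, ybar = ybar, ssw = ssw, n = length(values), m = nlevels(f))
}

# Negative profiled REML criterion at variance ratio gamma (>= 0).
.reml_crit <- function(gamma, st) {
  w <- st$ni / (1 + st$ni * gamma)
  W <- sum(w)
  mu <- sum(w * st$ybar) / W
  Q <- sum(st$ssw) + sum(w * (st$ybar - mu)^2)
  (st$n - 1) * log(Q) + sum(log1p(st$ni * gamma)) + log(W)
}

# Full REML log-likelihood at gamma with the profiled residual variance.
.reml_loglik <- function(gamma, st) {
  w <- st$ni / (1 + st$ni * gamma)
  W <- sum(w)
  mu <- sum(w * st$ybar) / W
  Q <- sum(st$ssw) + sum(w * (st$ybar - mu)^2)
  s2e <- Q / (st$n - 1)
  -0.5 * ((st$n - 1) * (log(2 * pi * s2e) + 1) +
            sum(log1p(st$ni * gamma)) + log(W))
}

#' REML fit of the one-way random-intercept model
#'
#' @param values Numeric response (e.g. event dates in days).
#' @param ids Individual identifiers, parallel to `values`.
#' @return List: `sigma2_id`, `sigma2_res`, `mu`, `loglik` (REML),
#'   `loglik_null` (REML log-likelihood with sigma2_id = 0), `n_ind`,
#'   `n_obs`.
#' @export
fit_random_intercept <- function(values, ids) {
  st <- .group_stats(values, ids)
  if (st$m < 2) stop("need at least 2 individuals")
  if (all(st$ni < 2)) {
    stop("all individuals have a single observation; ",
         "sigma2_id is inestimable")
  }
  f <- function(lg) .reml_crit(exp(lg), st)
  opt <- stats::optimize(f, interval = c(-12, 12), tol = 1e-10)
  gamma <- exp(opt$minimum)
  if (.reml_crit(0, st) <= opt$objective) gamma <- 0   # boundary solution
  w <- st$ni / (1 + st$ni * gamma)
  W <- sum(w)
  mu <- sum(w * st$ybar) / W
  Q <- sum(st$ssw) + sum(w * (st$ybar - mu)^2)
  s2e <- Q / (st$n - 1)
  list(sigma2_id = gamma * s2e, sigma2_res = s2e, mu = mu,
       loglik = .reml_loglik(gamma, st),
       loglik_null = .reml_loglik(0, st),
       n_ind = st$m, n_obs = st$n)
}

#' Repeatability with parametric-bootstrap CI and boundary LRT
#'
#' R is the intraclass correlation from [fit_random_intercept()]. The 95%
#' confidence interval is the 2.5/97.5 percentile of R over `n_boot`
#' parametric-bootstrap refits (data regenerated from the fitted model on
#' the observed design). Significance of sigma2_id = 0 uses the REML
#' likelihood-ratio test with the boundary-corrected null distribution, an
#' equal mixture of a point mass at zero and chi-square(1).
#'
#' @param values,ids Response and individual identifiers.
#' @param n_boot Bootstrap iterations (0 = point estimate only).
#' @param seed Optional integer seed for the bootstrap.
#' @param ci_level Confidence level (default 0.95).
#' @return One-row data.frame: R, ci_low, ci_high, p_lrt, n_ind, n_obs,
#'   sigma2_id, sigma2_res, n_boot_failed.
#' @export
repeatability <- function(values, ids, n_boot = 1000, seed = NULL,
                          ci_level = 0.95) {
  fit <- fit_random_intercept(values, ids)
  R <- if (fit$sigma2_id + fit$sigma2_res > 0) {
    fit$sigma2_id / (fit$sigma2_id + fit$sigma2_res)
  } else 0
  lr <- max(0, 2 * (fit$loglik - fit$loglik_null))
  p_lrt <- if (lr <= 1e-10) 1 else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  ci <- c(NA_real_, NA_real_)
  n_failed <- 0L
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    st <- .group_stats(values, ids)
    sid <- sqrt(fit$sigma2_id); sres <- sqrt(fit$sigma2_res)
    Rb <- rep(NA_real_, n_boot)
    idx <- rep(seq_len(st$m), st$ni)
    for (b in seq_len(n_boot)) {
      a <- stats::rnorm(st$m, 0, sid)
      yb <- fit$mu + a[idx] + stats::rnorm(st$n, 0, sres)
      fb <- tryCatch(fit_random_intercept(yb, idx), error = function(e) NULL)
      if (is.null(fb)) { n_failed <- n_failed + 1L; next }
      tot <- fb$sigma2_id + fb$sigma2_res
      Rb[b] <- if (tot > 0) fb$sigma2_id / tot else 0
    }
    if (n_failed > 0.2 * n_boot) {
      warning(n_failed, " of ", n_boot, " bootstrap refits failed")
    }
    alpha <- (1 - ci_level) / 2
    ci <- stats::quantile(Rb, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  }
  data.frame(R = R, ci_low = ci[1], ci_high = ci[2], p_lrt = p_lrt,
             n_ind = fit$n_ind, n_obs = fit$n_obs,
             sigma2_id = fit$sigma2_id, sigma2_res = fit$sigma2_res,
             n_boot_failed = n_failed)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Vector of p-values.
#' @return Step-up adjusted p-values (order-preserving, each >= raw p).
#' @export
fdr_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Per-band repeatability profile
#'
#' One repeatability estimate per 1-degree latitudinal band holding data of
#' the requested kind from at least `min_ind` individuals (and at least one
#' individual observed in two years, otherwise the variance ratio is
#' inestimable and the band is skipped). FDR adjustment is applied across
#' the profile.
#'
#' @param obs Band observations ([band_entry_dates()] /
#'   [band_lon_deviation()] rows, possibly many birds and years).
#' @param kind "entry_date" or "lon_deviation".
#' @param direction "south" or "north".
#' @param min_ind Minimum number of individuals per band (default 2).
#' @param n_boot,seed Passed to [repeatability()]; per-band seeds are
#'   derived from `seed`.
#' @return Data.frame: band_low_lat, kind, direction, R, ci_low, ci_high,
#'   p_lrt, p_fdr, n_ind, n_obs.
#' @export
band_repeatability_profile <- function(obs, kind, direction, min_ind = 2,
                                       n_boot = 1000, seed = NULL) {
  obs <- obs[obs$kind == kind & obs$direction == direction, , drop = FALSE]
  out <- list()
  for (band in sort(unique(obs$band_low_lat))) {
    ob <- obs[obs$band_low_lat == band, , drop = FALSE]
    if (length(unique(ob$bird_id)) < min_ind) next
    if (max(table(ob$bird_id)) < 2) next
    bseed <- if (is.null(seed)) NULL else (seed + band) %% .Machine$integer.max
    est <- tryCatch(
      repeatability(ob$value, ob$bird_id, n_boot = n_boot, seed = bseed),
      error = function(e) NULL)
    if (is.null(est)) next
    est <- cbind(data.frame(band_low_lat = band, kind = kind,
                            direction = direction, stringsAsFactors = FALSE),
                 est)
    out[[length(out) + 1]] <- est
  }
  if (length(out) == 0) {
    return(data.frame(band_low_lat = integer(), kind = character(),
                      direction = character(), R = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_lrt = numeric(), p_fdr = numeric(),
                      n_ind = integer(), n_obs = integer(),
                      stringsAsFactors = FALSE))
  }
  prof <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  prof$p_fdr <- fdr_adjust(prof$p_lrt)
  prof
}

.EVENTS <- c("breeding_arrival", "breeding_departure",
             "wintering_arrival", "wintering_departure",
             "south_stopover_start", "south_stopover_end",
             "south_stopover_duration")

#' Repeatability of annual-event timing
#'
#' One estimate per event variable (arrival/departure at breeding and
#' wintering, south-bound stopover start/end/duration). Variables with
#' fewer than two individuals observed in repeat years are skipped with a
#' message. FDR adjustment is applied across the estimated set.
#'
#' @param events Event table from [event_table()].
#' @param n_boot,seed Passed to [repeatability()].
#' @return Data.frame: event, R, ci_low, ci_high, p_lrt, p_fdr, n_ind, n_obs.
#' @export
event_repeatability <- function(events, n_boot = 1000, seed = NULL) {
  out <- list()
  for (k in seq_along(.EVENTS)) {
    ev <- .EVENTS[k]
    e <- events[events$event == ev, , drop = FALSE]
    reps <- table(e$bird_id)
    if (length(reps) < 2 || sum(reps >= 2) < 2) {
      message("event ", ev, ": fewer than 2 individuals with repeat years; skipped")
      next
    }
    eseed <- if (is.null(seed)) NULL else (seed + k) %% .Machine$integer.max
    est <- tryCatch(
      repeatability(e$value, e$bird_id, n_boot = n_boot, seed = eseed),
      error = function(err) NULL)
    if (is.null(est)) next
    out[[length(out) + 1]] <- cbind(data.frame(event = ev,
                                               stringsAsFactors = FALSE), est)
  }
  if (length(out) == 0) {
    return(data.frame(event = character(), R = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p_lrt = numeric(), p_fdr = numeric(),
                      n_ind = integer(), n_obs = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$p_fdr <- fdr_adjust(res$p_lrt)
  res
}
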