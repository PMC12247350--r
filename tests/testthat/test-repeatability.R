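sim_grouped <- function(m, k, s_id, s_res, mu = 0, seed = 1) {
  set.seed(seed)
  ids <- rep(seq_len(m), each = k)
  list(values = mu + rnorm(m, 0, sqrt(s_id))[ids] + rnorm(m * k, 0, sqrt(s_res)),
       ids = ids)
}

test_that("profiled REML matches lme4 on unbalanced data", {
  set.seed(3)
  ids <- rep(1:25, times = sample(1:4, 25, replace = TRUE))
  y <- 10 + rnorm(25, 0, 2)[ids] + rnorm(length(ids), 0, 1)
  fit <- fit_random_intercept(y, ids)
  m <- lme4::lmer(y ~ 1 + (1 | g), data = data.frame(y = y, g = factor(ids)),
                  REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$sigma2_id, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_res, vc$vcov[2], tolerance = 1e-6)
  expect_equal(fit$mu, unname(lme4::fixef(m)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
})

test_that("REML equals the balanced one-way ANOVA closed form", {
  d <- sim_grouped(20, 4, s_id = 3, s_res = 1.5, seed = 8)
  fit <- fit_random_intercept(d$values, d$ids)
  k <- 4
  ybar_i <- tapply(d$values, d$ids, mean)
  msb <- k * sum((ybar_i - mean(d$values))^2) / (20 - 1)
  msw <- sum((d$values - ybar_i[d$ids])^2) / (20 * (k - 1))
  expect_equal(fit$sigma2_res, msw, tolerance = 1e-6)
  expect_equal(fit$sigma2_id, (msb - msw) / k, tolerance = 1e-6)
})

test_that("variance components are recovered in a Monte-Carlo experiment", {
  d <- sim_grouped(200, 5, s_id = 4, s_res = 1, seed = 10)
  fit <- fit_random_intercept(d$values, d$ids)
  expect_lt(abs(fit$sigma2_id - 4) / 4, 0.15)
  expect_lt(abs(fit$sigma2_res - 1) / 1, 0.15)
})

test_that("degenerate structures behave at the boundaries", {
  # constant within individuals: R -> 1
  ids <- rep(1:10, each = 3)
  vals <- rnorm(10)[ids]
  r <- repeatability(vals, ids, n_boot = 0)
  expect_gt(r$R, 0.999)
  # permuted ids: sigma2_id at or near zero
  d <- sim_grouped(30, 3, s_id = 0, s_res = 1, seed = 12)
  fit <- fit_random_intercept(d$values, d$ids)
  expect_lt(fit$sigma2_id, 0.1)
  # all singletons: inestimable
  expect_error(fit_random_intercept(rnorm(5), 1:5), "single observation")
  expect_error(fit_random_intercept(rnorm(3), c(1, 1, 1)), "2 individuals")
})

test_that("R is invariant to affine transforms of the response", {
  d <- sim_grouped(30, 3, s_id = 2, s_res = 1, seed = 13)
  r1 <- repeatability(d$values, d$ids, n_boot = 0)
  r2 <- repeatability(3.7 * d$values - 21, d$ids, n_boot = 0)
  expect_equal(r1$R, r2$R, tolerance = 1e-6)
  expect_equal(r1$p_lrt, r2$p_lrt, tolerance = 1e-6)
})

test_that("bootstrap CIs are reproducible, optional, and cover the estimate", {
  d <- sim_grouped(30, 3, s_id = 1.5, s_res = 1, seed = 14)
  r0 <- repeatability(d$values, d$ids, n_boot = 0)
  expect_true(is.na(r0$ci_low) && is.na(r0$ci_high))
  r1 <- repeatability(d$values, d$ids, n_boot = 300, seed = 9)
  r2 <- repeatability(d$values, d$ids, n_boot = 300, seed = 9)
  expect_equal(r1, r2)
  expect_lte(r1$ci_low, r1$R + 0.02)
  expect_gte(r1$ci_high, r1$R - 0.02)
})

test_that("bootstrap CI width shrinks as individuals are added", {
  widths <- vapply(c(10, 30, 100), function(m) {
    d <- sim_grouped(m, 3, s_id = 1.5, s_res = 1, seed = 100 + m)
    r <- repeatability(d$values, d$ids, n_boot = 300, seed = 1)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("BH step-up adjustment matches hand-computed values", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696,
         0.762, 0.94, 0.942, 0.975, 1)
  adj <- fdr_adjust(p)
  # step-up: adj_i = min over j >= i of p_j * n / j (hand-computable)
  n <- length(p)
  want <- rev(cummin(rev(p * n / seq_len(n))))
  expect_equal(adj, pmin(1, want))
  expect_true(all(adj >= p))
})

test_that("band profiles skip sparse bands and respect identical data", {
  obs <- data.frame(
    bird_id = rep(c("a", "b", "c"), each = 2),
    cycle_year = rep(c(2020, 2021), 3),
    direction = "south", band_low_lat = 40L, kind = "entry_date",
    value = c(10, 12, 20, 19, 30, 33), stringsAsFactors = FALSE)
  # duplicate the band at another latitude: identical estimates
  obs2 <- obs; obs2$band_low_lat <- 41L
  prof <- band_repeatability_profile(rbind(obs, obs2), "entry_date", "south",
                                     n_boot = 0)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$R[1], prof$R[2])
  # a band with a single individual is dropped
  solo <- obs[1:2, ]; solo$band_low_lat <- 50L; solo$bird_id <- "z"
  prof2 <- band_repeatability_profile(rbind(obs, solo), "entry_date", "south",
                                      n_boot = 0)
  expect_false(50L %in% prof2$band_low_lat)
})

test_that("event repeatability is shift-invariant and clone-invariant", {
  set.seed(15)
  ev <- expand.grid(bird_id = sprintf("b%02d", 1:12), cycle_year = 2020:2022,
                    event = c("breeding_arrival", "wintering_arrival"),
                    stringsAsFactors = FALSE)
  icpt <- rnorm(12, 0, 5)
  names(icpt) <- sprintf("b%02d", 1:12)
  ev$value <- 150 + icpt[ev$bird_id] + rnorm(nrow(ev), 0, 3)
  r1 <- suppressMessages(event_repeatability(ev, n_boot = 0))
  ev_shift <- ev; ev_shift$value <- ev$value + 40
  r2 <- suppressMessages(event_repeatability(ev_shift, n_boot = 0))
  expect_equal(r1$R, r2$R, tolerance = 1e-6)
  clones <- ev; clones$bird_id <- paste0(clones$bird_id, "_clone")
  r3 <- suppressMessages(event_repeatability(rbind(ev, clones), n_boot = 0))
  # invariance to cloning is exact under ML; REML's fixed-effect correction
  # shifts the estimate by O(1/n_ind)
  expect_equal(r3$R, r1$R, tolerance = 0.05)
  # a variable with too few repeat individuals is skipped with a message
  ev_small <- ev[ev$bird_id == "b01", ]
  expect_message(out <- event_repeatability(ev_small, n_boot = 0), "skipped")
})
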