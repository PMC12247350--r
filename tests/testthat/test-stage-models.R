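# Simulated fidelity records with stage-specific zero-inflation and beta
# means, plus an optional bird effect on the conditional logit scale.
sim_overlap_records <- function(n_birds = 100, years = 2, zi, mu, phi = 20,
                                sd_bird = 0, seed = 1) {
  set.seed(seed)
  stages <- names(zi)
  b_eff <- rnorm(n_birds, 0, sd_bird)
  rows <- list()
  for (b in seq_len(n_birds)) {
    for (st in stages) {
      for (y in seq_len(years)) {
        zero <- runif(1) < zi[[st]]
        if (zero) {
          v <- 0
        } else {
          m <- plogis(qlogis(mu[[st]]) + b_eff[b])
          v <- rbeta(1, m * phi, (1 - m) * phi)
        }
        rows[[length(rows) + 1]] <- data.frame(
          bird_id = sprintf("b%03d", b), stage = st, year_x = 2019 + y,
          any_overlap = v > 0, overlap_prop = v,
          min_center_dist_km = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("the zero-inflated beta mixed model recovers stage parameters", {
  zi <- c(breeding = 0.7, south_migration = 0.7, wintering = 0.1,
          north_migration = 0.9)
  mu <- c(breeding = 0.2, south_migration = 0.2, wintering = 0.5,
          north_migration = 0.1)
  recs <- sim_overlap_records(100, 2, zi, mu, sd_bird = 0.3, seed = 2)
  fit <- fit_zib_mixed(recs)
  expect_s3_class(fit, "stage_model_fit")
  # recovered zero-inflation probabilities and beta means per stage
  stages <- sort(names(zi))
  X <- stats::model.matrix(~stage, data.frame(stage = factor(stages)))
  zi_hat <- plogis(as.numeric(X %*% fit$zero_inflation$estimate))
  mu_hat <- plogis(as.numeric(X %*% fit$conditional$estimate))
  expect_true(all(abs(zi_hat - zi[stages]) < 0.1))
  expect_true(all(abs(mu_hat - mu[stages]) < 0.1))
  # the wintering stage is significantly less zero-inflated than breeding
  zrow <- fit$zero_inflation[fit$zero_inflation$term == "stagewintering", ]
  expect_lt(zrow$estimate, 0)
  expect_lt(zrow$p, 0.05)
})

test_that("exact-1 overlaps are shrunk and counted", {
  zi <- c(a = 0.5, b = 0.5)
  mu <- c(a = 0.5, b = 0.5)
  recs <- sim_overlap_records(40, 2, zi, mu, seed = 3)
  recs$overlap_prop[c(1, 5)] <- 1
  fit <- fit_zib_mixed(recs)
  expect_equal(fit$n_shrunk, 2)
  expect_error(fit_zib_mixed(recs[recs$stage == "a", ]), "2 stages")
})

test_that("relabeling stages permutes the fitted stage means identically", {
  zi <- c(a = 0.6, b = 0.3, c = 0.1)
  mu <- c(a = 0.2, b = 0.4, c = 0.6)
  recs <- sim_overlap_records(60, 2, zi, mu, seed = 4)
  fit1 <- fit_zib_mixed(recs)
  relab <- c(a = "x3", b = "x1", c = "x2")
  recs2 <- recs; recs2$stage <- relab[recs2$stage]
  fit2 <- fit_zib_mixed(recs2)
  stage_means <- function(fit, stages) {
    X <- stats::model.matrix(~stage, data.frame(stage = factor(stages)))
    plogis(as.numeric(X %*% fit$conditional$estimate))
  }
  m1 <- stage_means(fit1, sort(names(zi)))
  m2 <- stage_means(fit2, sort(unname(relab)))
  # x1 = b, x2 = c, x3 = a
  expect_equal(m2, m1[c(2, 3, 1)], tolerance = 1e-4)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
})

test_that("ZIB log-likelihood decomposes into Bernoulli and beta parts without a bird effect", {
  zi <- c(a = 0.4, b = 0.2)
  mu <- c(a = 0.3, b = 0.6)
  recs <- sim_overlap_records(80, 2, zi, mu, sd_bird = 0, seed = 5)
  fit <- fit_zib_mixed(recs)
  # independent per-part fits: logistic regression on the zero indicator,
  # beta regression on the non-zero records
  d <- recs
  d$z <- d$overlap_prop == 0
  ll_bern <- as.numeric(stats::logLik(stats::glm(z ~ stage, binomial(), d)))
  nz <- d[!d$z, ]
  ll_beta <- as.numeric(stats::logLik(glmmTMB::glmmTMB(
    overlap_prop ~ stage, family = glmmTMB::beta_family(), data = nz)))
  expect_equal(fit$loglik, ll_bern + ll_beta, tolerance = 0.1)
})

test_that("the Gaussian distance model detects the wintering contrast", {
  set.seed(6)
  stages <- c("breeding", "south_migration", "wintering", "north_migration")
  recs <- expand.grid(bird_id = sprintf("b%03d", 1:100), stage = stages,
                      stringsAsFactors = FALSE)
  b_eff <- rnorm(100, 0, 10)
  names(b_eff) <- sprintf("b%03d", 1:100)
  base <- c(breeding = 160, south_migration = 250, wintering = 10,
            north_migration = 400)
  recs$min_center_dist_km <- pmax(0, base[recs$stage] + b_eff[recs$bird_id] +
                                    rnorm(nrow(recs), 0, 40))
  fit <- fit_gaussian_mixed(recs)
  wrow <- fit$coefficients[fit$coefficients$term == "stagewintering", ]
  expect_lt(wrow$estimate, 0)
  expect_lt(wrow$p, 0.01)
  # identical distances: all stage contrasts are zero
  recs2 <- recs; recs2$min_center_dist_km <- 100
  fit2 <- fit_gaussian_mixed(recs2)
  ct <- fit2$coefficients[grepl("^stage", fit2$coefficients$term), ]
  expect_true(all(abs(ct$estimate) < 1e-8))
})

test_that("balanced Gaussian REML matches the closed-form ANOVA decomposition", {
  set.seed(7)
  m <- 40; stages <- c("a", "b", "c", "d")
  recs <- expand.grid(bird_id = sprintf("b%02d", 1:m), stage = stages,
                      stringsAsFactors = FALSE)
  b_eff <- rnorm(m, 0, 5)
  names(b_eff) <- sprintf("b%02d", 1:m)
  mu <- c(a = 10, b = 20, c = 30, d = 40)
  recs$min_center_dist_km <- mu[recs$stage] + b_eff[recs$bird_id] +
    rnorm(nrow(recs), 0, 2)
  fit <- fit_gaussian_mixed(recs)
  # two-way balanced decomposition: sigma2_id = (MS_bird - MS_err) / k
  a <- stats::aov(min_center_dist_km ~ stage + bird_id, data = recs)
  ms <- summary(a)[[1]][["Mean Sq"]]
  k <- length(stages)
  expect_equal(fit$sigma2_res, ms[3], tolerance = 1e-6)
  expect_equal(fit$sigma2_id, (ms[2] - ms[3]) / k, tolerance = 1e-6)
})
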