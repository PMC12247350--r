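# Stage comparison of site-fidelity metrics.
# Model 1: zero-inflated beta mixed model for the between-year overlap
#   proportion (logit P(no overlap) ~ stage; logit mean of the non-zero beta
#   part ~ stage; bird random intercept on the conditional part).
# Model 2: Gaussian mixed model for the minimum centroid distance.

#' Zero-inflated beta mixed model for overlap proportion (model 1)
#'
#' Fits `overlap_prop ~ stage + (1 | bird_id)` with a `~ stage`
#' zero-inflation part and a beta conditional part (logit links, common
#' precision) by maximum likelihood through glmmTMB. Overlap values of
#' exactly 1 are shrunk to `1 - eps` (the beta support is open); the number
#' of shrunk records is reported. Stages in which every record is zero
#' leave that stage's conditional coefficient inestimable and are flagged.
#'
#' @param records Fidelity records ([fidelity_records()]): columns
#'   `overlap_prop`, `stage`, `bird_id`.
#' @param eps Shrinkage for exact ones (default 1e-6).
#' @return List of class `stage_model_fit`: `model = "overlap_zib"`, `fit`
#'   (the glmmTMB object), `conditional` and `zero_inflation` coefficient
#'   tables (estimate, se, z, p on the link scale), `sigma2_id`, `loglik`,
#'   `n_shrunk`, `inestimable_stages`.
#' @export
fit_zib_mixed <- function(records, eps = 1e-6) {
  stopifnot(all(c("overlap_prop", "stage", "bird_id") %in% names(records)))
  if (length(unique(records$stage)) < 2) stop("need at least 2 stages")
  if (any(records$overlap_prop < 0 | records$overlap_prop > 1)) {
    stop("overlap_prop outside [0, 1]")
  }
  d <- records
  n_shrunk <- sum(d$overlap_prop >= 1)
  d$overlap_prop[d$overlap_prop >= 1] <- 1 - eps
  d$stage <- factor(d$stage)
  all_zero <- vapply(split(d$overlap_prop, d$stage),
                     function(v) all(v == 0), logical(1))
  fit <- glmmTMB::glmmTMB(
    overlap_prop ~ stage + (1 | bird_id),
    ziformula = ~stage,
    family = glmmTMB::beta_family(link = "logit"),
    data = d)
  if (!is.null(fit$fit$convergence) && fit$fit$convergence != 0) {
    stop("zero-inflated beta model did not converge: ", fit$fit$message)
  }
  sm <- summary(fit)
  coef_table <- function(part) {
    cc <- sm$coefficients[[part]]
    data.frame(term = rownames(cc), estimate = cc[, 1], se = cc[, 2],
               z = cc[, 3], p = cc[, 4], row.names = NULL,
               stringsAsFactors = FALSE)
  }
  vc <- glmmTMB::VarCorr(fit)$cond$bird_id
  structure(list(model = "overlap_zib", fit = fit,
                 conditional = coef_table("cond"),
                 zero_inflation = coef_table("zi"),
                 sigma2_id = as.numeric(vc[1, 1]),
                 loglik = as.numeric(stats::logLik(fit)),
                 n_shrunk = n_shrunk,
                 inestimable_stages = names(all_zero)[all_zero]),
            class = "stage_model_fit")
}

#' Gaussian mixed model for minimum centroid distance (model 2)
#'
#' REML fit of `min_center_dist_km ~ stage + (1 | bird_id)` with
#' normal-approximation Wald tests on the stage contrasts.
#'
#' @param records Fidelity records with `min_center_dist_km`, `stage`,
#'   `bird_id`.
#' @param log_transform Fit on log(distance + 1 km)? Default FALSE.
#' @return `stage_model_fit` list: `model = "distance_gaussian"`, `fit`
#'   (merMod), `coefficients` table, `sigma2_id`, `sigma2_res`, `loglik`,
#'   `singleton_stages` (stages with one record, whose contrast is
#'   unreliable).
#' @export
fit_gaussian_mixed <- function(records, log_transform = FALSE) {
  stopifnot(all(c("min_center_dist_km", "stage", "bird_id") %in% names(records)))
  if (any(!is.finite(records$min_center_dist_km))) stop("non-finite distances")
  d <- records
  d$stage <- factor(d$stage)
  d$y <- if (log_transform) log(d$min_center_dist_km + 1) else d$min_center_dist_km
  singleton <- names(which(table(d$stage) < 2))
  fit <- lme4::lmer(y ~ stage + (1 | bird_id), data = d, REML = TRUE)
  cc <- tryCatch(suppressWarnings(summary(fit)$coefficients),
                 error = function(e) NULL)
  if (is.null(cc)) {
    # degenerate fits (e.g. zero residual variance) have no usable vcov
    fe <- lme4::fixef(fit)
    cc <- cbind(Estimate = fe, `Std. Error` = NA_real_, `t value` = NA_real_)
  }
  coefs <- data.frame(term = rownames(cc), estimate = cc[, 1], se = cc[, 2],
                      z = cc[, 1] / cc[, 2],
                      p = 2 * stats::pnorm(abs(cc[, 1] / cc[, 2]),
                                           lower.tail = FALSE),
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)
  structure(list(model = "distance_gaussian", fit = fit,
                 coefficients = coefs,
                 sigma2_id = as.numeric(vc$bird_id[1, 1]),
                 sigma2_res = attr(vc, "sc")^2,
                 loglik = as.numeric(stats::logLik(fit)),
                 log_transform = log_transform,
                 singleton_stages = singleton),
            class = "stage_model_fit")
}

#' @exportS3Method base::print
print.stage_model_fit <- function(x, ...) {
  cat("Stage model:", x$model, "\n")
  cat("log-likelihood:", format(x$loglik, digits = 6),
      " bird-intercept variance:", format(x$sigma2_id, digits = 4), "\n")
  if (x$model == "overlap_zib") {
    cat("\nConditional (beta, logit mean):\n")
    print(x$conditional, digits = 3)
    cat("\nZero-inflation (logit P(no overlap)):\n")
    print(x$zero_inflation, digits = 3)
    if (x$n_shrunk > 0) cat("\n", x$n_shrunk, "exact-1 overlap value(s) shrunk\n")
    if (length(x$inestimable_stages) > 0) {
      cat("all-zero stage(s):", paste(x$inestimable_stages, collapse = ", "), "\n")
    }
  } else {
    cat("\nFixed effects (km):\n")
    print(x$coefficients, digits = 3)
  }
  invisible(x)
}
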