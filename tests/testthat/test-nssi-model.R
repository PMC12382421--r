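# brute-force helpers used as independent oracles
obs_ll_scalar <- function(y, eta, pi, k) {
  mu <- exp(eta)
  if (y == 0) log(pi + (1 - pi) * (k / (k + mu))^k)
  else log(1 - pi) + dnbinom(y, size = k, mu = mu, log = TRUE)
}

tiny_count_data <- function() {
  data.frame(id = rep(1:3, each = 4), arm = rep(c(1, 0, 1), each = 4),
             week = rep(0:3, 3), count = c(0, 2, 1, 0, 3, 0, 5, 2, 0, 0, 1, 0))
}

test_that("with no zero inflation and no random effects the likelihood is plain NB", {
  d <- tiny_count_data()
  p <- list(beta = c(0.5, 0.2, -0.05, -0.1), zero_inflation = 0,
            dispersion = 1.2, re_sd = c(0, 0), re_corr = 0)
  eta <- p$beta[1] + p$beta[2] * d$arm + p$beta[3] * d$week +
    p$beta[4] * d$arm * d$week
  expect_equal(zinb_loglik(p, d),
               sum(dnbinom(d$count, size = 1.2, mu = exp(eta), log = TRUE)))
})

test_that("duplicating the dataset doubles the log-likelihood", {
  d <- tiny_count_data()
  p <- list(beta = c(0.5, 0.2, -0.05, -0.1), zero_inflation = 0.25,
            dispersion = 1.2, re_sd = c(0.5, 0.08), re_corr = 0.3)
  d2 <- d; d2$id <- d2$id + 10
  expect_equal(zinb_loglik(p, rbind(d, d2)), 2 * zinb_loglik(p, d),
               tolerance = 1e-8)
})

test_that("adaptive quadrature matches dense-grid numerical integration", {
  d <- tiny_count_data()
  p <- list(beta = c(0.5, 0.2, -0.05, -0.1), zero_inflation = 0.25,
            dispersion = 1.2, re_sd = c(0.5, 0.08), re_corr = 0.3)
  Sigma <- matrix(c(0.25, 0.3 * 0.5 * 0.08, 0.3 * 0.5 * 0.08, 0.0064), 2)
  Si <- solve(Sigma)
  gb0 <- seq(-8, 8, length.out = 641) * 0.5
  gb1 <- seq(-8, 8, length.out = 641) * 0.08
  bg <- as.matrix(expand.grid(b0 = gb0, b1 = gb1))
  brute <- 0
  for (i in unique(d$id)) {
    sub <- d[d$id == i, ]
    xb <- p$beta[1] + p$beta[2] * sub$arm + p$beta[3] * sub$week +
      p$beta[4] * sub$arm * sub$week
    f <- numeric(nrow(bg))
    for (j in seq_len(nrow(sub)))
      f <- f + vapply(xb[j] + bg[, 1] + bg[, 2] * sub$week[j],
                      function(e) obs_ll_scalar(sub$count[j], e, 0.25, 1.2),
                      numeric(1))
    f <- f - 0.5 * (Si[1, 1] * bg[, 1]^2 + 2 * Si[1, 2] * bg[, 1] * bg[, 2] +
                      Si[2, 2] * bg[, 2]^2)
    brute <- brute + log(sum(exp(f)) * diff(gb0)[1] * diff(gb1)[1] /
                           (2 * pi * sqrt(det(Sigma))))
  }
  expect_equal(zinb_loglik(p, d, method = "aghq", nq = 15), brute,
               tolerance = 1e-4)
  # Laplace is close but not exact on such small counts
  expect_equal(zinb_loglik(p, d, method = "laplace"), brute, tolerance = 0.01)
})

test_that("parameter validation and degenerate data are rejected", {
  d <- tiny_count_data()
  p_ok <- list(beta = c(0, 0, 0, 0), zero_inflation = 0.2, dispersion = 1,
               re_sd = c(0.1, 0.1), re_corr = 0)
  expect_error(zinb_loglik(modifyList(p_ok, list(dispersion = -1)), d),
               "dispersion")
  expect_error(zinb_loglik(modifyList(p_ok, list(zero_inflation = 1)), d),
               "zero_inflation")
  expect_error(zinb_loglik(p_ok, d[0, ]), "empty")
  dd <- d; dd$count <- dd$count + 0.5
  expect_error(zinb_loglik(p_ok, dd), "integer")
  dz <- d; dz$count <- 0
  expect_error(fit_zinb_glmm(dz), "degenerate")
  expect_error(fit_zinb_glmm(d[d$arm == 1, ]), "per arm")
})

test_that("the fitted optimum dominates the generating parameters in likelihood", {
  cfg <- trial_config(n_per_arm = 40, weeks_of_weekly_obs = 9,
                      irr_treatment_by_time = 0.95, zero_inflation = 0.2,
                      control_weekly_trend = 1, missing_rate_followup = 0,
                      seed = 71)
  t <- generate_trial(cfg)
  d <- t$weekly; names(d)[names(d) == "nssi_count"] <- "count"
  fit <- fit_zinb_glmm(d, restarts = 1, hessian = FALSE)
  mu0 <- 2.8 / 0.8
  truth <- list(beta = c(log(mu0) - 0.6^2 / 2, 0, 0, log(0.95)),
                zero_inflation = 0.2, dispersion = 1.5, re_sd = c(0.6, 0.02),
                re_corr = 0)
  expect_gte(fit$loglik, zinb_loglik(truth, d) - 1e-6)
})

test_that("estimates agree with glmmTMB on a simulated trial", {
  skip_if_not_installed("glmmTMB")
  cfg <- trial_config(n_per_arm = 100, weeks_of_weekly_obs = 10,
                      irr_treatment_by_time = 0.95, zero_inflation = 0.2,
                      control_weekly_trend = 1, missing_rate_followup = 0,
                      seed = 33)
  t <- generate_trial(cfg)
  d <- t$weekly; names(d)[names(d) == "nssi_count"] <- "count"
  d$a <- as.numeric(d$arm == "intervention")
  g <- suppressWarnings(glmmTMB::glmmTMB(
    count ~ a * week + (1 + week | id), ziformula = ~1,
    family = glmmTMB::nbinom2, data = d))
  f <- fit_zinb_glmm(d, restarts = 1, hessian = FALSE)
  expect_equal(unname(f$params$beta), unname(glmmTMB::fixef(g)$cond),
               tolerance = 1e-3)
  expect_equal(f$params$zero_inflation,
               unname(plogis(glmmTMB::fixef(g)$zi)), tolerance = 1e-3)
  expect_equal(f$params$dispersion, unname(glmmTMB::sigma(g)), tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-4)
})

test_that("with zero inflation pinned at 0 the fit tracks a Poisson mixed model on Poisson data", {
  skip_if_not_installed("lme4")
  set.seed(91)
  n <- 120; wks <- 0:7
  b0 <- rnorm(n, 0, 0.4)
  a <- rep(c(1, 0), each = n / 2)
  d <- expand.grid(id = 1:n, week = wks)
  d$arm <- a[d$id]
  eta <- 0.8 + 0.1 * d$arm - 0.03 * d$week - 0.04 * d$arm * d$week + b0[d$id]
  d$count <- rpois(nrow(d), exp(eta))
  f <- fit_zinb_glmm(d, restarts = 1, hessian = FALSE,
                     fix = list(zero_inflation = 0, re_corr = 0))
  g <- lme4::glmer(count ~ arm * week + (1 | id), data = d, family = poisson)
  expect_equal(unname(f$params$beta), unname(lme4::fixef(g)), tolerance = 0.05)
  expect_gt(f$params$dispersion, 5)   # dispersion escapes to the Poisson limit
})

test_that("fit output is structurally sound and reportable", {
  cfg <- trial_config(n_per_arm = 30, weeks_of_weekly_obs = 8,
                      missing_rate_followup = 0, seed = 44)
  t <- generate_trial(cfg)
  d <- t$weekly; names(d)[names(d) == "nssi_count"] <- "count"
  f <- fit_zinb_glmm(d, restarts = 1, contrast_weeks = c(7))
  expect_s3_class(f, "zinb_fit")
  expect_true(all(f$irr$estimate > 0))
  ok <- !is.na(f$irr$lower)
  expect_true(all(f$irr$lower[ok] <= f$irr$estimate[ok] &
                    f$irr$estimate[ok] <= f$irr$upper[ok]))
  path <- withr::local_tempfile(fileext = ".json")
  write_zinb_report(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$params$dispersion, f$params$dispersion)
  expect_output(print(f), "Zero-inflated")
})
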