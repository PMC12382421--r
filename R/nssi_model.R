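#' Zero-inflated negative binomial mixed model for weekly NSSI counts
#'
#' The primary-outcome model: weekly NSSI counts y_ij for participant i at
#' week t_j follow a zero-inflated negative binomial,
#'   P(y = 0)  = pi + (1 - pi) NB(0 | mu_ij, k)
#'   P(y = y+) = (1 - pi) NB(y | mu_ij, k),
#' with log mu_ij = b_0 + b_arm a_i + b_wk t_j + b_int a_i t_j + u_i + v_i t_j
#' and bivariate Gaussian random intercept/slope (u_i, v_i). The
#' treatment-by-time coefficient exponentiates to the weekly incidence rate
#' ratio (IRR). The zero-inflation probability is intercept-only (the data
#' give no covariate structure for the structural-zero process). The marginal
#' likelihood integrates the random effects per subject by a Laplace
#' approximation (default) or adaptive Gauss-Hermite quadrature.
#'
#' @name nssi_model
NULL

# Gauss-Hermite nodes/weights (physicists', weight exp(-x^2)) by Golub-Welsch.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# per-observation ZINB log-density at log-mean eta
zinb_obs_ll <- function(y, eta, pi, k) {
  mu <- exp(pmin(eta, 30))
  ll <- numeric(length(y))
  z <- y == 0
  lnb0 <- k * (log(k) - log(k + mu[z]))
  ll[z] <- if (pi > 0) log(pi + (1 - pi) * exp(lnb0)) else lnb0
  if (any(!z))
    ll[!z] <- log(1 - pi) + stats::dnbinom(y[!z], size = k, mu = mu[!z], log = TRUE)
  ll
}

# first/second derivatives of the per-observation log-density wrt eta
zinb_obs_derivs <- function(y, eta, pi, k) {
  mu <- exp(pmin(eta, 30))
  u <- numeric(length(y)); d2 <- numeric(length(y))
  z <- y == 0
  if (any(z)) {
    muz <- mu[z]
    p0 <- exp(k * (log(k) - log(k + muz)))
    s <- pi + (1 - pi) * p0
    q <- -k * muz / (k + muz)
    qp <- -k^2 * muz / (k + muz)^2
    g <- (1 - pi) * p0 * q / s
    u[z] <- g
    d2[z] <- (1 - pi) * p0 * (q^2 + qp) / s - g^2
  }
  if (any(!z)) {
    yn <- y[!z]; mun <- mu[!z]
    u[!z] <- yn - (yn + k) * mun / (k + mun)
    d2[!z] <- -(yn + k) * k * mun / (k + mun)^2
  }
  list(u = u, w = -d2)   # w = negative curvature (usually >= 0)
}

# Vectorized damped Newton for the per-subject random-effect modes.
# g: subject index (integer), t: week, y: count, xb: fixed linear predictor,
# P: 2x2 precision of the random effects. Returns modes and the 2x2 negative
# Hessian entries of the joint log-density at the mode.
inner_modes <- function(y, t, g, n_sub, xb, pi, k, P, b_start = NULL,
                        max_iter = 50L, tol = 1e-8) {
  b0 <- if (is.null(b_start)) numeric(n_sub) else b_start[, 1]
  b1 <- if (is.null(b_start)) numeric(n_sub) else b_start[, 2]
  fval <- function(b0, b1) {
    eta <- xb + b0[g] + b1[g] * t
    ll <- rowsum_vec(zinb_obs_ll(y, eta, pi, k), g, n_sub)
    ll - 0.5 * (P[1, 1] * b0^2 + 2 * P[1, 2] * b0 * b1 + P[2, 2] * b1^2)
  }
  f <- fval(b0, b1)
  for (it in seq_len(max_iter)) {
    eta <- xb + b0[g] + b1[g] * t
    d <- zinb_obs_derivs(y, eta, pi, k)
    g1 <- rowsum_vec(d$u, g, n_sub) - (P[1, 1] * b0 + P[1, 2] * b1)
    g2 <- rowsum_vec(d$u * t, g, n_sub) - (P[1, 2] * b0 + P[2, 2] * b1)
    A11 <- rowsum_vec(d$w, g, n_sub) + P[1, 1]
    A12 <- rowsum_vec(d$w * t, g, n_sub) + P[1, 2]
    A22 <- rowsum_vec(d$w * t * t, g, n_sub) + P[2, 2]
    # ridge-damp any non-PD subject blocks
    det_a <- A11 * A22 - A12^2
    bad <- det_a <= 1e-10 | A11 <= 1e-10
    if (any(bad)) {
      ridge <- pmax(1e-3, -pmin(A11[bad], A22[bad]) + 1e-3)
      A11[bad] <- A11[bad] + ridge; A22[bad] <- A22[bad] + ridge
      det_a <- A11 * A22 - A12^2
    }
    s0 <- (A22 * g1 - A12 * g2) / det_a
    s1 <- (A11 * g2 - A12 * g1) / det_a
    if (max(abs(g1), abs(g2)) < tol) break
    step <- rep(1, n_sub)
    for (h in 1:12) {
      f_new <- fval(b0 + step * s0, b1 + step * s1)
      worse <- f_new < f - 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    b0 <- b0 + step * s0; b1 <- b1 + step * s1
    f <- fval(b0, b1)
    if (max(abs(step * s0), abs(step * s1)) < tol) break
  }
  eta <- xb + b0[g] + b1[g] * t
  d <- zinb_obs_derivs(y, eta, pi, k)
  A11 <- rowsum_vec(d$w, g, n_sub) + P[1, 1]
  A12 <- rowsum_vec(d$w * t, g, n_sub) + P[1, 2]
  A22 <- rowsum_vec(d$w * t * t, g, n_sub) + P[2, 2]
  det_a <- pmax(A11 * A22 - A12^2, 1e-12)
  list(b = cbind(b0, b1), f = f, A11 = A11, A12 = A12, A22 = A22,
       det_a = det_a)
}

rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

validate_zinb_params <- function(params) {
  stopifnot(is.list(params))
  if (length(params$beta) != 4) stop("beta must have 4 elements", call. = FALSE)
  if (!(params$zero_inflation >= 0 && params$zero_inflation < 1))
    stop("zero_inflation must lie in [0, 1)", call. = FALSE)
  if (params$dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  sds <- params$re_sd
  if (length(sds) != 2 || any(sds < 0)) stop("re_sd must be 2 nonnegative values",
                                             call. = FALSE)
  rho <- params$re_corr %||% 0
  if (abs(rho) > 1) stop("re_corr must lie in [-1, 1]", call. = FALSE)
  invisible(params)
}

prepare_zinb_data <- function(data) {
  need <- c("id", "arm", "week", "count")
  if (!all(need %in% names(data)))
    stop("data needs columns id, arm, week, count", call. = FALSE)
  if (nrow(data) == 0) stop("empty data", call. = FALSE)
  y <- data$count
  if (anyNA(y)) { data <- data[!is.na(y), ]; y <- data$count }
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be nonnegative integers", call. = FALSE)
  a <- if (is.numeric(data$arm)) as.numeric(data$arm)
       else as.numeric(data$arm == "intervention")
  gf <- factor(data$id)
  list(y = as.numeric(y), t = as.numeric(data$week), a = a,
       g = as.integer(gf), ids = levels(gf), n_sub = nlevels(gf))
}

#' Marginal log-likelihood of the ZINB mixed model
#'
#' Integrates the bivariate random effect per participant: Laplace
#' approximation by default, adaptive Gauss-Hermite quadrature on request.
#' When both random-effect SDs are zero the integral degenerates and the
#' plain zero-inflated negative binomial log-likelihood is returned.
#'
#' @param params list with `beta` (intercept, arm, week, arm:week on the
#'   log-mean scale), `zero_inflation` in [0, 1), `dispersion` k > 0,
#'   `re_sd` (SD of random intercept and slope) and `re_corr`.
#' @param data long data frame: `id`, `arm` (0/1 or "control"/
#'   "intervention"), `week`, `count`.
#' @param method `"laplace"` or `"aghq"`.
#' @param nq quadrature nodes per dimension for `"aghq"`.
#' @return Marginal log-likelihood (scalar).
#' @export
zinb_loglik <- function(params, data, method = c("laplace", "aghq"), nq = 9) {
  method <- match.arg(method)
  validate_zinb_params(params)
  d <- prepare_zinb_data(data)
  beta <- params$beta
  xb <- beta[1] + beta[2] * d$a + beta[3] * d$t + beta[4] * d$a * d$t
  pi <- params$zero_inflation; k <- params$dispersion
  sds <- params$re_sd; rho <- params$re_corr %||% 0
  if (all(sds < 1e-8))
    return(sum(zinb_obs_ll(d$y, xb, pi, k)))
  if (any(sds < 1e-8))
    stop("degenerate single-zero random-effect SD unsupported; use both > 0 or both 0",
         call. = FALSE)
  Sigma <- matrix(c(sds[1]^2, rho * sds[1] * sds[2],
                    rho * sds[1] * sds[2], sds[2]^2), 2)
  sum(zinb_marginal_ll(d, xb, pi, k, Sigma, method, nq)$ll)
}

# per-subject marginal log-likelihood components
zinb_marginal_ll <- function(d, xb, pi, k, Sigma, method, nq, b_start = NULL) {
  P <- solve(Sigma)
  ldS <- determinant(Sigma, logarithm = TRUE)$modulus[1]
  m <- inner_modes(d$y, d$t, d$g, d$n_sub, xb, pi, k, P, b_start = b_start)
  if (method == "laplace") {
    ll <- m$f - 0.5 * ldS - 0.5 * log(m$det_a)
    return(list(ll = ll, modes = m$b))
  }
  gh <- gauss_hermite(nq)
  # per-subject Cholesky of A^{-1}: A = U'U upper => L = U^{-1}
  u11 <- sqrt(m$A11); u12 <- m$A12 / u11
  u22 <- sqrt(pmax(m$A22 - u12^2, 1e-12))
  # L = [[1/u11, -u12/(u11*u22)], [0, 1/u22]], det L = 1/(u11*u22)
  acc <- matrix(0, d$n_sub, 1)
  f0 <- m$f
  total <- numeric(d$n_sub)
  for (q1 in seq_len(nq)) for (q2 in seq_len(nq)) {
    x1 <- gh$nodes[q1]; x2 <- gh$nodes[q2]
    db0 <- sqrt(2) * (x1 / u11 - x2 * u12 / (u11 * u22))
    db1 <- sqrt(2) * (x2 / u22)
    b0 <- m$b[, 1] + db0; b1 <- m$b[, 2] + db1
    eta <- xb + b0[d$g] + b1[d$g] * d$t
    f <- rowsum_vec(zinb_obs_ll(d$y, eta, pi, k), d$g, d$n_sub) -
      0.5 * (P[1, 1] * b0^2 + 2 * P[1, 2] * b0 * b1 + P[2, 2] * b1^2)
    total <- total + gh$weights[q1] * gh$weights[q2] *
      exp(f - f0 + x1^2 + x2^2)
  }
  ll <- f0 + log(total) + log(2) - log(u11 * u22) - log(2 * pi_const) - 0.5 * ldS
  list(ll = ll, modes = m$b)
}

pi_const <- base::pi

#' Fit the ZINB mixed model and report incidence rate ratios
#'
#' Maximizes the marginal likelihood over the fixed effects, zero-inflation
#' probability, dispersion and random-effect covariance (log/logit/atanh
#' transformed internally), restarting from a set of fixed jittered starts
#' and keeping the best likelihood (ties broken by the first start). Wald
#' confidence intervals come from the numerical Hessian at the optimum.
#'
#' @param data long data frame: `id`, `arm`, `week`, `count`.
#' @param contrast_weeks weeks at which between-group rate ratios
#'   `exp(b_arm + b_int * week)` are reported (defaults to the 1-month and
#'   3-month posttreatment assessment weeks).
#' @param method integration method, `"laplace"` (default) or `"aghq"`.
#' @param restarts number of jittered starts (>= 1).
#' @param fix named list pinning parameters during optimization, e.g.
#'   `list(zero_inflation = 0)`; names among `zero_inflation`, `dispersion`,
#'   `re_corr`.
#' @param conf_level confidence level for Wald intervals.
#' @param hessian if `FALSE`, skip the numerical Hessian (point estimates
#'   only; CIs are `NA`). Useful in simulation loops.
#' @param control passed to [stats::nlminb()].
#' @return Object of class `"zinb_fit"`: `params`, `irr` (data frame of
#'   labeled rate-ratio contrasts with CIs), `loglik`, `vcov` (transformed
#'   scale), `converged`, `diagnostics`.
#' @export
fit_zinb_glmm <- function(data, contrast_weeks = c(16, 24),
                          method = c("laplace", "aghq"), restarts = 3,
                          fix = list(), conf_level = 0.95, hessian = TRUE,
                          control = list()) {
  method <- match.arg(method)
  d <- prepare_zinb_data(data)
  if (all(d$y == 0))
    stop("degenerate data: all counts are zero; zero-inflation and mean are unidentified",
         call. = FALSE)
  if (length(unique(d$a)) < 2 || min(table(d$a[!duplicated(d$g)])) < 2)
    stop("need at least 2 participants per arm", call. = FALSE)
  if (length(unique(d$t)) < 2) stop("need at least 2 time points", call. = FALSE)

  # starts: Poisson GLM for the fixed effects, moment-flavored defaults for the rest
  st_glm <- tryCatch(stats::glm.fit(cbind(1, d$a, d$t, d$a * d$t), d$y,
                                    family = stats::poisson())$coefficients,
                     error = function(e) c(log(mean(d$y) + 0.1), 0, 0, 0))
  st_glm[!is.finite(st_glm)] <- 0
  theta0 <- c(st_glm, stats::qlogis(0.15), log(1), log(0.5), log(0.02), 0)
  names(theta0) <- c("b0", "b_arm", "b_wk", "b_int", "lgt_pi", "log_k",
                     "log_sd0", "log_sd1", "atanh_rho")
  lower <- c(rep(-Inf, 4), -7, log(0.05), log(1e-3), log(1e-3), -3)
  upper <- c(rep(Inf, 4), 7, log(50), log(5), log(5), 3)

  fixed_idx <- integer(0); fixed_val <- numeric(0)
  map_fix <- c(zero_inflation = 5L, dispersion = 6L, re_corr = 9L)
  for (nm in names(fix)) {
    if (!nm %in% names(map_fix)) stop("unknown fix name: ", nm, call. = FALSE)
    i <- map_fix[[nm]]
    v <- switch(nm,
                zero_inflation = if (fix[[nm]] <= 0) -20 else stats::qlogis(fix[[nm]]),
                dispersion = log(fix[[nm]]),
                re_corr = atanh(fix[[nm]]))
    fixed_idx <- c(fixed_idx, i); fixed_val <- c(fixed_val, v)
  }
  free <- setdiff(seq_along(theta0), fixed_idx)

  env <- new.env()
  env$b_warm <- NULL
  negll <- function(th_free) {
    th <- theta0
    th[free] <- th_free
    th[fixed_idx] <- fixed_val
    pi <- stats::plogis(th[5]); k <- exp(th[6])
    sd0 <- exp(th[7]); sd1 <- exp(th[8]); rho <- tanh(th[9])
    Sigma <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2)
    xb <- th[1] + th[2] * d$a + th[3] * d$t + th[4] * d$a * d$t
    res <- tryCatch(
      zinb_marginal_ll(d, xb, pi, k, Sigma, method, nq = 9, b_start = env$b_warm),
      error = function(e) NULL)
    if (is.null(res) || !all(is.finite(res$ll))) return(1e10)
    env$b_warm <- res$modes
    -sum(res$ll)
  }

  # fixed jitter pattern: reproducible multi-start
  jit <- rbind(rep(0, 9),
               c(0.2, 0, 0, 0, 1.0, 0.5, 0.4, 0.5, 0),
               c(-0.2, 0, 0, 0, -1.0, -0.5, -0.4, -0.5, 0.5))
  fits <- vector("list", max(1, restarts))
  for (r in seq_len(max(1, restarts))) {
    start <- theta0 + jit[((r - 1) %% nrow(jit)) + 1, ]
    env$b_warm <- NULL
    fits[[r]] <- tryCatch(
      stats::nlminb(start[free], negll, lower = lower[free], upper = upper[free],
                    control = utils::modifyList(
                      list(iter.max = 400, eval.max = 600, rel.tol = 1e-9),
                      control)),
      error = function(e) list(objective = Inf, convergence = 1L,
                               message = conditionMessage(e)))
  }
  objs <- vapply(fits, function(f) f$objective, numeric(1))
  best <- which.min(objs)           # ties: which.min takes the first start
  opt <- fits[[best]]
  if (!is.finite(opt$objective)) stop("ZINB fit failed on all starts", call. = FALSE)
  converged <- identical(opt$convergence, 0L)
  if (!converged)
    warning("ZINB optimizer did not report convergence: ",
            opt$message %||% "", call. = FALSE)

  th <- theta0; th[free] <- opt$par; th[fixed_idx] <- fixed_val
  H <- if (hessian)
    tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
  else NULL
  V_free <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  V <- matrix(NA_real_, 9, 9, dimnames = list(names(theta0), names(theta0)))
  if (!is.null(V_free)) V[free, free] <- V_free

  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  irr_row <- function(label, est_log, var_log) {
    se <- sqrt(var_log)
    data.frame(label = label, estimate = exp(est_log),
               lower = exp(est_log - zc * se), upper = exp(est_log + zc * se),
               stringsAsFactors = FALSE)
  }
  rows <- list(irr_row("weekly treatment-by-time IRR", th[4], V[4, 4]))
  for (w in contrast_weeks) {
    v <- V[2, 2] + w^2 * V[4, 4] + 2 * w * V[2, 4]
    rows <- c(rows, list(irr_row(sprintf("group rate ratio at week %g", w),
                                 th[2] + w * th[4], v)))
  }
  irr <- do.call(rbind, rows)

  params <- list(beta = stats::setNames(th[1:4], c("intercept", "arm", "week",
                                                   "arm_week")),
                 zero_inflation = unname(stats::plogis(th[5])),
                 dispersion = unname(exp(th[6])),
                 re_sd = c(intercept = unname(exp(th[7])),
                           slope = unname(exp(th[8]))),
                 re_corr = unname(tanh(th[9])))
  structure(list(params = params, theta = th, loglik = -opt$objective,
                 vcov = V, irr = irr, converged = converged, method = method,
                 diagnostics = list(restart_negll = objs, best_start = best,
                                    message = opt$message %||% NULL,
                                    n_subjects = d$n_sub, n_obs = length(d$y))),
            class = "zinb_fit")
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat("Zero-inflated negative binomial mixed model (", x$method, ")\n", sep = "")
  cat(sprintf("  subjects: %d, observations: %d, logLik: %.3f%s\n",
              x$diagnostics$n_subjects, x$diagnostics$n_obs, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  zero-inflation: %.3f, dispersion k: %.3f, RE sd: (%.3f, %.4f), corr %.2f\n",
              x$params$zero_inflation, x$params$dispersion,
              x$params$re_sd[1], x$params$re_sd[2], x$params$re_corr))
  print(x$irr, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a JSON parameter report for a fitted ZINB model
#'
#' @param fit a `"zinb_fit"`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_zinb_report <- function(fit, path) {
  stopifnot(inherits(fit, "zinb_fit"))
  jsonlite::write_json(list(params = fit$params, irr = fit$irr,
                            loglik = fit$loglik, converged = fit$converged,
                            ci_method = "Wald (numerical Hessian)",
                            integration = fit$method),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
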