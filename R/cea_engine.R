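#' Baseline-adjusted between-arm difference
#'
#' Least-squares regression of the outcome on the arm indicator plus an
#' optional baseline covariate; the arm coefficient is the adjusted
#' difference (intervention minus control). With identical regressors in the
#' cost and effect equations this per-equation estimate coincides with the
#' joint seemingly-unrelated-regression estimate, so the cross-equation
#' correlation is carried entirely by the patient-level bootstrap.
#'
#' @param data data frame with the analysis variables.
#' @param outcome name of the outcome column.
#' @param arm name of the arm column (0/1 or "control"/"intervention").
#' @param baseline optional name of the baseline covariate column; `NULL`
#'   for an unadjusted difference (e.g. remission, which is not
#'   baseline-adjusted).
#' @return List: `delta` (arm coefficient), `coefficients`, `residuals`.
#' @export
adjusted_diff <- function(data, outcome, arm = "arm", baseline = NULL) {
  a <- data[[arm]]
  if (!is.numeric(a)) a <- as.numeric(a == "intervention")
  y <- data[[outcome]]
  x <- if (!is.null(baseline)) data[[baseline]] else NULL
  res <- adj_diff_core(y, a, x)
  res
}

# closed-form least squares for y ~ 1 + a (+ x); returns arm coefficient
adj_diff_core <- function(y, a, x = NULL) {
  if (anyNA(y) || (!is.null(x) && anyNA(x)))
    stop("missing values in analysis variables; impute first", call. = FALSE)
  n1 <- sum(a == 1); n0 <- sum(a == 0)
  if (n1 < 2 || n0 < 2) stop("need at least 2 participants per arm", call. = FALSE)
  if (is.null(x)) {
    m1 <- sum(y[a == 1]) / n1; m0 <- sum(y[a == 0]) / n0
    co <- c(intercept = m0, arm = m1 - m0)
    return(list(delta = m1 - m0, coefficients = co,
                residuals = y - ifelse(a == 1, m1, m0)))
  }
  n <- length(y)
  Sa <- n1; Sx <- sum(x); Sax <- sum(a * x); Sxx <- sum(x * x)
  Sy <- sum(y); Say <- sum(a * y); Sxy <- sum(x * y)
  XtX <- matrix(c(n, Sa, Sx,
                  Sa, Sa, Sax,
                  Sx, Sax, Sxx), 3, 3)
  beta <- tryCatch(solve(XtX, c(Sy, Say, Sxy)),
                   error = function(e) stop("collinear baseline covariate",
                                            call. = FALSE))
  fit <- beta[1] + beta[2] * a + beta[3] * x
  list(delta = beta[2],
       coefficients = c(intercept = beta[1], arm = beta[2], baseline = beta[3]),
       residuals = y - fit)
}

#' Outcome specification for the CEA engine
#'
#' @param label short outcome label (e.g. `"qaly_1m"`).
#' @param cost,effect column names of accumulated cost and effect.
#' @param baseline_cost,baseline_effect baseline-adjustment covariate column
#'   names (`NULL` = unadjusted, as for remission).
#' @param direction `+1` if a larger effect is better as coded (QALYs,
#'   remission), `-1` to flip the arm difference into "episodes averted"
#'   (control minus intervention) for NSSI frequency, so that improvement is
#'   always positive on the cost-effectiveness plane.
#' @return List of class `"outcome_spec"`.
#' @export
outcome_spec <- function(label, cost, effect, baseline_cost = NULL,
                         baseline_effect = NULL, direction = 1) {
  stopifnot(direction %in% c(-1, 1))
  structure(list(label = label, cost = cost, effect = effect,
                 baseline_cost = baseline_cost,
                 baseline_effect = baseline_effect, direction = direction),
            class = "outcome_spec")
}

#' Patient-level bootstrap nested within multiple imputations
#'
#' For each imputed dataset m and bootstrap iteration b, participants are
#' resampled with replacement stratified by arm (arm sizes preserved
#' exactly), and the baseline-adjusted cost and effect differences are
#' recomputed on the resample, giving one (delta-cost, delta-effect) draw.
#' Draw (m, b) runs on its own deterministic substream of `seed`.
#'
#' @param imputed list of completed data frames (from [mice_pmm()] or a
#'   single complete dataset wrapped in `list()`).
#' @param spec an [outcome_spec()].
#' @param B bootstrap iterations per imputation (>= 1).
#' @param seed master seed.
#' @return Data frame of class `"ce_draws"`: `imputation`, `boot`, `dC`,
#'   `dE`, with attributes `points` (per-imputation full-data estimates) and
#'   `label`.
#' @export
bootstrap_cea <- function(imputed, spec, B = 5000, seed = 1L) {
  stopifnot(inherits(spec, "outcome_spec"), B >= 1)
  if (is.data.frame(imputed)) imputed <- list(imputed)
  M <- length(imputed)
  stopifnot(M >= 1)
  draws <- vector("list", M)
  points <- data.frame(imputation = seq_len(M), dC = NA_real_, dE = NA_real_)
  for (m in seq_len(M)) {
    dat <- imputed[[m]]
    a <- dat$arm
    if (!is.numeric(a)) a <- as.numeric(a == "intervention")
    yc <- dat[[spec$cost]]; ye <- dat[[spec$effect]]
    xc <- if (!is.null(spec$baseline_cost)) dat[[spec$baseline_cost]]
    xe <- if (!is.null(spec$baseline_effect)) dat[[spec$baseline_effect]]
    if (is.logical(ye)) ye <- as.numeric(ye)
    points$dC[m] <- adj_diff_core(yc, a, xc)$delta
    points$dE[m] <- spec$direction * adj_diff_core(ye, a, xe)$delta
    i1 <- which(a == 1); i0 <- which(a == 0)
    n1 <- length(i1); n0 <- length(i0)
    dC <- numeric(B); dE <- numeric(B)
    for (b in seq_len(B)) {
      idx <- with_seed(substream_seed(seed, m, b),
                       c(i1[sample.int(n1, n1, replace = TRUE)],
                         i0[sample.int(n0, n0, replace = TRUE)]))
      ab <- a[idx]
      dC[b] <- adj_diff_core(yc[idx], ab, if (!is.null(xc)) xc[idx])$delta
      dE[b] <- spec$direction *
        adj_diff_core(ye[idx], ab, if (!is.null(xe)) xe[idx])$delta
    }
    draws[[m]] <- data.frame(imputation = m, boot = seq_len(B), dC = dC, dE = dE)
  }
  out <- do.call(rbind, draws)
  attr(out, "points") <- points
  attr(out, "label") <- spec$label
  class(out) <- c("ce_draws", "data.frame")
  out
}

#' Pool bootstrap-within-imputation draws into a CEA result
#'
#' Point estimates are the mean of the per-imputation full-data estimates
#' (Rubin's rule for means); uncertainty is summarized by percentile
#' intervals over the stacked M x B draws. The ICER interval is the
#' percentile interval of the per-draw ratios, excluding (but counting)
#' draws whose |delta-effect| is below `tol` where the ratio is undefined;
#' quadrant proportions accompany the ratio because percentile ratio
#' intervals are sign-ambiguous across quadrants.
#'
#' @param draws a `"ce_draws"` data frame.
#' @param conf_level confidence level for percentile intervals.
#' @param tol effect magnitude below which a draw's ratio is excluded.
#' @return List of class `"ce_result"`.
#' @export
pool_cea <- function(draws, conf_level = 0.95, tol = 1e-12) {
  stopifnot(inherits(draws, "ce_draws"), nrow(draws) >= 1)
  pts <- attr(draws, "points")
  alpha <- (1 - conf_level) / 2
  qs <- c(alpha, 1 - alpha)
  dC <- mean(pts$dC); dE <- mean(pts$dE)
  ok <- abs(draws$dE) > tol
  ratio_ci <- if (any(ok)) stats::quantile(draws$dC[ok] / draws$dE[ok], qs,
                                           names = FALSE) else c(NA_real_, NA_real_)
  res <- list(label = attr(draws, "label"),
              dC = dC, dE = dE,
              icer = if (abs(dE) > tol) dC / dE else NA_real_,
              ci_dC = stats::quantile(draws$dC, qs, names = FALSE),
              ci_dE = stats::quantile(draws$dE, qs, names = FALSE),
              ci_icer = ratio_ci,
              n_ratio_excluded = sum(!ok),
              quadrants = ce_plane(draws)$proportions,
              M = max(draws$imputation), B = max(draws$boot),
              conf_level = conf_level)
  class(res) <- "ce_result"
  res
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("CEA result [%s]: M=%d imputations x B=%d bootstrap draws\n",
              x$label %||% "?", x$M, x$B))
  cat(sprintf("  delta-cost  %10.2f  (%.0f%% CI %.2f to %.2f)\n", x$dC,
              100 * x$conf_level, x$ci_dC[1], x$ci_dC[2]))
  cat(sprintf("  delta-effect %9.5f  (%.0f%% CI %.5f to %.5f)\n", x$dE,
              100 * x$conf_level, x$ci_dE[1], x$ci_dE[2]))
  cat(sprintf("  ICER %.2f  (percentile CI %.2f to %.2f; %d draws excluded)\n",
              x$icer, x$ci_icer[1], x$ci_icer[2], x$n_ratio_excluded))
  cat("  plane quadrants:",
      paste(sprintf("%s=%.3f", names(x$quadrants), x$quadrants), collapse = " "),
      "\n")
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' `delta-cost / delta-effect` on pooled point estimates, with the plane
#' quadrant attached as context: a bare ratio is ambiguous (a negative ICER
#' can mean dominance or being dominated).
#'
#' @param dC incremental cost (intervention minus control, USD).
#' @param dE incremental effect (improvement positive).
#' @return Numeric of class `"icer"` with attribute `context`.
#' @export
icer <- function(dC, dE) {
  if (dE == 0) stop("delta-effect is zero: ICER undefined; report dominance/quadrant instead",
                    call. = FALSE)
  ctx <- if (dE > 0 && dC > 0) "northeast: more effective, more costly"
  else if (dE > 0 && dC <= 0) "dominant: more effective, cost-saving"
  else if (dE < 0 && dC >= 0) "dominated: less effective, more costly"
  else "southwest: less effective, cost-saving"
  structure(dC / dE, class = "icer", context = ctx)
}

#' @export
print.icer <- function(x, ...) {
  cat(sprintf("ICER: %.2f per effect unit [%s]\n", unclass(x),
              attr(x, "context")))
  invisible(x)
}

#' Net monetary benefit
#'
#' `lambda * delta-effect - delta-cost` at willingness-to-pay `lambda`.
#'
#' @param lambda nonnegative willingness-to-pay (vectorized).
#' @param dC,dE incremental cost and effect.
#' @return Money (same units as `dC`).
#' @export
nmb <- function(lambda, dC, dE) {
  if (any(lambda < 0)) stop("negative willingness-to-pay", call. = FALSE)
  lambda * dE - dC
}

#' Default willingness-to-pay grid
#'
#' 0 to 200,000 in steps of 1,000 (USD per effect unit), covering the
#' Swedish reference value of 84,000 per QALY.
#' @return Numeric vector.
#' @export
default_lambda_grid <- function() seq(0, 200000, by = 1000)

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of draws with positive
#' net monetary benefit (`lambda * dE - dC > 0`, strict).
#'
#' @param draws a `"ce_draws"` data frame (or any data frame with `dC`,
#'   `dE`).
#' @param lambdas nondecreasing willingness-to-pay grid.
#' @return Data frame of class `"ceac"`: `lambda`, `prob_ce`.
#' @export
ceac <- function(draws, lambdas = default_lambda_grid()) {
  if (nrow(draws) == 0) stop("empty draws", call. = FALSE)
  if (any(lambdas < 0) || any(diff(lambdas) < 0))
    stop("lambdas must be nonnegative and nondecreasing", call. = FALSE)
  prob <- vapply(lambdas, function(l) mean(l * draws$dE - draws$dC > 0),
                 numeric(1))
  structure(data.frame(lambda = lambdas, prob_ce = prob),
            class = c("ceac", "data.frame"))
}

#' Cost-effectiveness plane summary
#'
#' Classifies each draw by the signs of (delta-effect, delta-cost):
#' NE (+,+), SE (+,-), NW (-,+), SW (-,-). Tie rule: draws lying exactly on
#' an axis are assigned to the east half (`dE = 0` counts as effective) and
#' the north half (`dC = 0` counts as costly), so proportions always sum
#' to 1.
#'
#' @param draws a `"ce_draws"` data frame.
#' @return List: `proportions` (named NE/NW/SE/SW) and `table` (the per-draw
#'   dE, dC pairs for plotting).
#' @export
ce_plane <- function(draws) {
  if (nrow(draws) == 0) stop("empty draws", call. = FALSE)
  east <- draws$dE >= 0
  north <- draws$dC >= 0
  prop <- c(NE = mean(east & north), NW = mean(!east & north),
            SE = mean(east & !north), SW = mean(!east & !north))
  list(proportions = prop,
       table = data.frame(dE = draws$dE, dC = draws$dC))
}
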