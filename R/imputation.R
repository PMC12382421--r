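#' Specification for multiple imputation
#'
#' Defaults (M = 20 imputations, 20 cycles, 5 donors) follow common practice
#' for trial-sized datasets; all are configuration, none is data-driven.
#'
#' @param M number of imputed datasets (>= 1).
#' @param iterations chained-equation cycles per imputation (>= 1).
#' @param k_donors donors for predictive mean matching (>= 1).
#' @param seed master seed; each imputation runs on its own substream.
#' @return List of class `"imputation_spec"`.
#' @export
imputation_spec <- function(M = 20, iterations = 20, k_donors = 5, seed = 1L) {
  stopifnot(M >= 1, iterations >= 1, k_donors >= 1)
  structure(list(M = as.integer(M), iterations = as.integer(iterations),
                 k_donors = as.integer(k_donors), seed = as.integer(seed)),
            class = "imputation_spec")
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Cycles Bayesian linear regressions over the incomplete variables: for each
#' target variable, regression parameters are drawn from their approximate
#' posterior (normal draw of the coefficients, scaled-inverse-chi-squared
#' draw of the residual variance), predicted means are computed for observed
#' rows (point estimate) and missing rows (parameter draw), and each missing
#' cell is filled with the observed value of one of the `k_donors` nearest
#' donors by predicted mean (type-1 matching). Every imputed value therefore
#' occurs among the observed values of its column. Fully observed variables
#' (always including the randomization arm) act as predictors only and are
#' never altered.
#'
#' @param data wide data frame; missing cells are `NA`. Non-numeric columns
#'   (e.g. `id`, `arm`) are used as predictors where sensible but never
#'   imputed; `arm` is encoded as an indicator predictor.
#' @param spec an [imputation_spec()].
#' @param exclude columns never used as predictors nor imputed (default
#'   `"id"`).
#' @return List of `M` data frames (class `"imputed_datasets"`), each with an
#'   attribute `imputed`: logical matrix flagging filled cells.
#' @export
mice_pmm <- function(data, spec = imputation_spec(), exclude = "id") {
  stopifnot(inherits(spec, "imputation_spec"), is.data.frame(data))
  work_cols <- setdiff(names(data), exclude)
  num_cols <- work_cols[vapply(data[work_cols], is.numeric, logical(1))]
  pred_extra <- setdiff(work_cols, num_cols)
  # factor-ish predictors (arm) become indicators
  X_extra <- NULL
  if (length(pred_extra)) {
    X_extra <- do.call(cbind, lapply(pred_extra, function(cl) {
      f <- factor(data[[cl]])
      if (anyNA(f)) stop(sprintf("non-numeric column '%s' must be fully observed", cl),
                         call. = FALSE)
      stats::model.matrix(~f)[, -1, drop = FALSE]
    }))
  }
  miss <- vapply(data[num_cols], anyNA, logical(1))
  all_missing <- vapply(data[num_cols], function(x) all(is.na(x)), logical(1))
  if (any(all_missing))
    stop(sprintf("variable(s) 100%% missing: %s",
                 paste(num_cols[all_missing], collapse = ", ")), call. = FALSE)
  targets <- num_cols[miss]
  if (!length(targets)) {
    out <- replicate(spec$M, data, simplify = FALSE)
    for (m in seq_along(out))
      attr(out[[m]], "imputed") <- matrix(FALSE, nrow(data), 0)
    class(out) <- "imputed_datasets"
    return(out)
  }
  na_mask <- is.na(as.matrix(data[targets]))
  colnames(na_mask) <- targets

  impute_once <- function(seed_m) with_seed(seed_m, {
    filled <- data
    # initialize each hole with a random observed donor
    for (v in targets) {
      obs <- filled[[v]][!is.na(filled[[v]])]
      filled[[v]][is.na(filled[[v]])] <- sample(obs, sum(is.na(filled[[v]])),
                                                replace = TRUE)
    }
    for (it in seq_len(spec$iterations)) {
      for (v in targets) {
        mis_rows <- which(na_mask[, v])
        obs_rows <- which(!na_mask[, v])
        preds <- setdiff(num_cols, v)
        X <- cbind(1, as.matrix(filled[preds]))
        if (!is.null(X_extra)) X <- cbind(X, X_extra)
        y <- data[[v]]
        Xo <- X[obs_rows, , drop = FALSE]; yo <- y[obs_rows]
        # ridge-stabilized least squares
        XtX <- crossprod(Xo) + diag(1e-6 * nrow(Xo), ncol(Xo))
        bhat <- solve(XtX, crossprod(Xo, yo))
        res <- yo - Xo %*% bhat
        df <- max(length(yo) - ncol(Xo), 1)
        sigma2 <- sum(res^2) / stats::rchisq(1, df)
        L <- chol(solve(XtX))
        bstar <- bhat + sqrt(sigma2) * t(L) %*% stats::rnorm(ncol(Xo))
        yhat_obs <- drop(Xo %*% bhat)
        yhat_mis <- drop(X[mis_rows, , drop = FALSE] %*% bstar)
        ord <- order(yhat_obs)
        yo_sorted <- yo[ord]; yh_sorted <- yhat_obs[ord]
        pos <- findInterval(yhat_mis, yh_sorted)
        k <- spec$k_donors
        n_obs <- length(yo_sorted)
        fill <- vapply(seq_along(mis_rows), function(jj) {
          p <- pos[jj]
          lo <- max(1, p - k); hi <- min(n_obs, p + k)
          cand <- lo:hi
          dd <- abs(yh_sorted[cand] - yhat_mis[jj])
          cand <- cand[order(dd)][seq_len(min(k, length(cand)))]
          yo_sorted[cand[sample.int(length(cand), 1)]]
        }, numeric(1))
        filled[[v]][mis_rows] <- fill
      }
    }
    attr(filled, "imputed") <- na_mask
    filled
  })

  out <- lapply(seq_len(spec$M), function(m)
    impute_once(substream_seed(spec$seed, m)))
  class(out) <- "imputed_datasets"
  out
}
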