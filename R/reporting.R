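#' Build the wide per-participant analysis dataset
#'
#' Joins accumulated costs under both perspectives, utilities/QALYs and
#' past-month NSSI counts into one row per participant. Masked measurements
#' are `NA`, ready for [mice_pmm()]. Accumulated cost at 3 months equals the
#' 1-month accumulation plus the 1-to-3-month period cost; baseline-period
#' costs are kept separate and only ever used as adjustment covariates.
#'
#' @param trial a `"ce_trial"` object.
#' @param cost_config list with `table` and `basis` (see
#'   [load_cost_config()]).
#' @param model a [mapping_model()].
#' @param exclude_categories resource-use categories dropped from costing
#'   (sensitivity analyses).
#' @return Wide data frame, one row per participant.
#' @export
build_analysis_data <- function(trial, cost_config = load_cost_config(),
                                model = default_mapping_model(),
                                exclude_categories = character(0)) {
  stopifnot(inherits(trial, "ce_trial"))
  parts <- trial$participants
  acc <- list()
  for (persp in c("healthcare", "societal")) {
    agg <- aggregate_costs(trial$resource_use, cost_config$table,
                           cost_config$basis, perspective = persp,
                           participants = parts,
                           exclude_categories = exclude_categories)
    acc[[persp]] <- accumulate_costs(agg)
  }
  out <- compute_outcomes(trial$assessments, model)
  out <- out[match(parts$id, out$id), ]
  hc <- acc$healthcare[match(parts$id, acc$healthcare$id), ]
  so <- acc$societal[match(parts$id, acc$societal$id), ]
  df <- data.frame(id = parts$id, arm = parts$arm,
                   hc_baseline = hc$baseline,
                   hc_post1m = hc$accum_post1m, hc_post3m = hc$accum_post3m,
                   soc_baseline = so$baseline,
                   soc_post1m = so$accum_post1m, soc_post3m = so$accum_post3m,
                   utility_baseline = out$utility_baseline,
                   stringsAsFactors = FALSE)
  for (cl in c("qaly_post1m", "qaly_post3m", "pm_nssi_baseline",
               "pm_nssi_post1m", "pm_nssi_post3m"))
    if (!is.null(out[[cl]])) df[[cl]] <- as.numeric(out[[cl]])
  rownames(df) <- NULL
  df
}

#' Analysis configuration for the full pipeline
#'
#' @param trial a [trial_config()] (the trial is generated) or a `"ce_trial"`
#'   object (used as-is).
#' @param cost_config list with `table`/`basis`; default is the bundled
#'   illustrative tariff.
#' @param mapping a [mapping_model()].
#' @param M,B imputations and bootstrap iterations per imputation.
#' @param imputation_iterations,k_donors chained-equation settings.
#' @param lambda_grid willingness-to-pay grid for the acceptability curves.
#' @param complete_case if `TRUE`, skip imputation and use complete cases
#'   only (sensitivity analysis).
#' @param exclude_categories resource-use categories excluded from costing
#'   (e.g. `c("school_absence_days", "school_presenteeism")`).
#' @param seed master seed for every stochastic stage.
#' @return List of class `"cea_config"`.
#' @export
cea_config <- function(trial = trial_config(), cost_config = load_cost_config(),
                       mapping = default_mapping_model(), M = 20, B = 5000,
                       imputation_iterations = 20, k_donors = 5,
                       lambda_grid = default_lambda_grid(),
                       complete_case = FALSE,
                       exclude_categories = character(0), seed = 1L) {
  structure(list(trial = trial, cost_config = cost_config, mapping = mapping,
                 M = M, B = B, imputation_iterations = imputation_iterations,
                 k_donors = k_donors, lambda_grid = lambda_grid,
                 complete_case = complete_case,
                 exclude_categories = exclude_categories, seed = seed),
            class = "cea_config")
}

pipeline_outcomes <- function() list(
  qaly_1m = outcome_spec("qaly_1m", cost = "COST_post1m", effect = "qaly_post1m",
                         baseline_cost = "COST_baseline",
                         baseline_effect = "utility_baseline"),
  qaly_3m = outcome_spec("qaly_3m", cost = "COST_post3m", effect = "qaly_post3m",
                         baseline_cost = "COST_baseline",
                         baseline_effect = "utility_baseline"),
  remission_1m = outcome_spec("remission_1m", cost = "COST_post1m",
                              effect = "remission_post1m",
                              baseline_cost = "COST_baseline"),
  remission_3m = outcome_spec("remission_3m", cost = "COST_post3m",
                              effect = "remission_post3m",
                              baseline_cost = "COST_baseline"),
  nssi_1m = outcome_spec("nssi_1m", cost = "COST_post1m",
                         effect = "pm_nssi_post1m",
                         baseline_cost = "COST_baseline",
                         baseline_effect = "pm_nssi_baseline", direction = -1),
  nssi_3m = outcome_spec("nssi_3m", cost = "COST_post3m",
                         effect = "pm_nssi_post3m",
                         baseline_cost = "COST_baseline",
                         baseline_effect = "pm_nssi_baseline", direction = -1))

#' Run the full within-trial cost-effectiveness pipeline
#'
#' Stages: simulate (or take) the trial, cost resource use under both
#' perspectives, construct outcomes, multiply impute missing follow-ups
#' (unless `complete_case`), derive remission from the completed past-month
#' counts, run the bootstrap-within-imputation CEA for each outcome and
#' perspective, and assemble acceptability curves, plane tables and a
#' reproducibility manifest. Any stage failure aborts with a stage-named
#' error.
#'
#' @param config a [cea_config()].
#' @param out_dir optional directory; when given, results (JSON), plane and
#'   CEAC tables (CSV) and the manifest are written there.
#' @return List of class `"cea_bundle"`: `analysis_data`, `results` (per
#'   outcome x perspective `ce_result`), `ceacs`, `planes`, `summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = cea_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cea_config"))
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))

  trial <- stage("simulate",
                 if (inherits(config$trial, "ce_trial")) config$trial
                 else generate_trial(config$trial))
  wide <- stage("cost+outcomes",
                build_analysis_data(trial, config$cost_config, config$mapping,
                                    config$exclude_categories))

  imputed <- stage("impute", {
    if (config$complete_case) {
      cc <- wide[stats::complete.cases(wide), , drop = FALSE]
      list(cc)
    } else {
      mice_pmm(wide, imputation_spec(M = config$M,
                                     iterations = config$imputation_iterations,
                                     k_donors = config$k_donors,
                                     seed = substream_seed(config$seed, 2L)))
    }
  })
  # derive remission from completed counts; map the perspective cost columns
  completed <- lapply(imputed, function(d) {
    d$remission_post1m <- as.numeric(d$pm_nssi_post1m == 0)
    d$remission_post3m <- as.numeric(d$pm_nssi_post3m == 0)
    d
  })

  specs <- pipeline_outcomes()
  results <- list(); ceacs <- list(); planes <- list()
  stage("analyze", for (persp in c("healthcare", "societal")) {
    pref <- if (persp == "healthcare") "hc" else "soc"
    datasets <- lapply(completed, function(d) {
      d$COST_baseline <- d[[paste0(pref, "_baseline")]]
      d$COST_post1m <- d[[paste0(pref, "_post1m")]]
      d$COST_post3m <- d[[paste0(pref, "_post3m")]]
      d
    })
    for (nm in names(specs)) {
      key <- paste(persp, nm, sep = ".")
      draws <- bootstrap_cea(datasets, specs[[nm]], B = config$B,
                             seed = substream_seed(config$seed, 3L,
                                                   match(key, outer_keys())))
      results[[key]] <- pool_cea(draws)
      ceacs[[key]] <- ceac(draws, config$lambda_grid)
      planes[[key]] <- ce_plane(draws)$table
    }
  })

  summary_tab <- stage("report", pipeline_summary(completed, results))
  manifest <- list(seed = config$seed, M = config$M, B = config$B,
                   complete_case = config$complete_case,
                   exclude_categories = config$exclude_categories,
                   n_participants = nrow(wide),
                   package_version = as.character(utils::packageVersion("ceatrial")),
                   config_hash = fnv1a(jsonlite::toJSON(
                     config[c("M", "B", "imputation_iterations", "k_donors",
                              "complete_case", "exclude_categories", "seed")],
                     auto_unbox = TRUE)),
                   results_hash = fnv1a(unlist(lapply(results, function(r)
                     sprintf("%.10g", c(r$dC, r$dE, r$icer, r$ci_dC, r$ci_dE))))))

  bundle <- structure(list(analysis_data = wide, results = results,
                           ceacs = ceacs, planes = planes,
                           summary = summary_tab, manifest = manifest),
                      class = "cea_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

outer_keys <- function() as.vector(outer(c("healthcare", "societal"),
                                         names(pipeline_outcomes()),
                                         paste, sep = "."))

pipeline_summary <- function(completed, results) {
  pooled_mean <- function(col, arm) mean(vapply(completed, function(d)
    mean(as.numeric(d[[col]][d$arm == arm])), numeric(1)))
  rows <- list()
  cols <- list(c("hc_post1m", "healthcare_costs", "post1m", FALSE),
               c("soc_post1m", "societal_costs", "post1m", FALSE),
               c("pm_nssi_post1m", "nssi_frequency", "post1m", TRUE),
               c("remission_post1m", "nssi_remission", "post1m", FALSE),
               c("qaly_post1m", "qalys", "post1m", FALSE),
               c("hc_post3m", "healthcare_costs", "post3m", FALSE),
               c("soc_post3m", "societal_costs", "post3m", FALSE),
               c("pm_nssi_post3m", "nssi_frequency", "post3m", TRUE),
               c("remission_post3m", "nssi_remission", "post3m", FALSE),
               c("qaly_post3m", "qalys", "post3m", FALSE))
  for (cc in cols) {
    mi <- pooled_mean(cc[1], "intervention"); mc <- pooled_mean(cc[1], "control")
    rows[[length(rows) + 1]] <- data.frame(
      timepoint = cc[3], outcome = cc[2], mean_intervention = mi,
      mean_control = mc, averted = as.logical(cc[4]), stringsAsFactors = FALSE)
  }
  summary_table(do.call(rbind, rows))
}

#' Summary table of arm means and differences
#'
#' Computes the unadjusted between-arm difference from full-precision arm
#' means: `mean_intervention - mean_control`, except rows flagged `averted`
#' (NSSI frequency), which report `mean_control - mean_intervention` so that
#' improvement is positive (episodes averted). Rounding happens only at
#' display time via [format_summary()]: costs to whole dollars, QALYs to 3
#' decimals, proportions to 2.
#'
#' @param arm_means data frame: `timepoint`, `outcome`, `mean_intervention`,
#'   `mean_control`, optional logical `averted`.
#' @return The input plus a `difference` column, class `"summary_table"`.
#' @export
summary_table <- function(arm_means) {
  need <- c("timepoint", "outcome", "mean_intervention", "mean_control")
  stopifnot(all(need %in% names(arm_means)))
  av <- arm_means$averted %||% rep(FALSE, nrow(arm_means))
  av[is.na(av)] <- FALSE
  arm_means$difference <- ifelse(av,
                                 arm_means$mean_control - arm_means$mean_intervention,
                                 arm_means$mean_intervention - arm_means$mean_control)
  class(arm_means) <- c("summary_table", "data.frame")
  arm_means
}

#' Display rounding for a summary table
#'
#' Costs to whole dollars, QALYs to 3 decimals, proportions (remission) to
#' 2, counts to 2. Internal values keep full precision; this is display-only.
#'
#' @param tab a [summary_table()].
#' @return Data frame of formatted character columns.
#' @export
format_summary <- function(tab) {
  digits <- ifelse(grepl("costs", tab$outcome), 0,
            ifelse(grepl("qaly", tab$outcome), 3, 2))
  fmt <- function(x) vapply(seq_along(x), function(i)
    formatC(round(x[i], digits[i]), format = "f", digits = digits[i],
            big.mark = ","), character(1))
  data.frame(timepoint = tab$timepoint, outcome = tab$outcome,
             mean_intervention = fmt(tab$mean_intervention),
             mean_control = fmt(tab$mean_control),
             difference = fmt(tab$difference), stringsAsFactors = FALSE)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(bundle$results)) {
    r <- bundle$results[[key]]
    jsonlite::write_json(r[setdiff(names(r), "")],
                         file.path(out_dir, paste0("result_", key, ".json")),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(bundle$ceacs[[key]],
                     file.path(out_dir, paste0("ceac_", key, ".csv")),
                     row.names = FALSE)
    utils::write.csv(bundle$planes[[key]],
                     file.path(out_dir, paste0("plane_", key, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(bundle$summary),
                   file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
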