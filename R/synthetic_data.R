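#' Configuration for the synthetic trial generator
#'
#' Builds and validates the parameter set for [generate_trial()]. Defaults
#' emulate a two-arm randomized trial of a 12-week internet-delivered therapy
#' adjunctive to usual care for adolescents with nonsuicidal self-injury
#' (NSSI): n = 83 per arm, weekly self-rated NSSI counts over 17 weeks,
#' assessments at baseline, week 16 (1 month posttreatment) and week 24
#' (3 months posttreatment), zero-inflated overdispersed counts with a
#' multiplicative treatment-by-time effect, right-skewed resource use
#' negatively correlated with health outcomes through a latent severity
#' factor, and missing-at-random follow-up data.
#'
#' @param n_per_arm participants per arm (>= 2).
#' @param weeks_of_weekly_obs number of weekly NSSI observations (weeks
#'   `0:(weeks_of_weekly_obs-1)` from randomization).
#' @param assessment_weeks strictly increasing week offsets of the assessment
#'   points; the first must be 0 (baseline).
#' @param baseline_nssi_weekly_mean expected observed weekly NSSI count at
#'   baseline (marginal over zero inflation).
#' @param control_weekly_trend multiplicative weekly trend of the NSSI mean in
#'   the control arm (1 = flat).
#' @param irr_treatment_by_time weekly incidence rate ratio of the
#'   treatment-by-time interaction (1 = no effect).
#' @param zero_inflation probability of a structural zero.
#' @param nb_dispersion negative binomial size parameter k (> 0); smaller is
#'   more overdispersed.
#' @param random_effect_sd_intercept,random_effect_sd_slope SDs of the
#'   per-subject random intercept and weekly slope on the log-mean scale.
#' @param baseline_utility_mean,baseline_utility_sd mean and SD of the
#'   baseline health utility (CHU9D-like scale in [0, 1]).
#' @param utility_effect arm difference in utility change reached at the first
#'   posttreatment assessment and maintained thereafter.
#' @param cost_means named list: expected resource-use quantity per category
#'   over a 12-week recall period, each a length-2 vector
#'   `c(intervention, control)` or a single value used for both arms.
#' @param cost_outcome_corr target sign/strength in [-1, 1] of the latent link
#'   between costs and outcomes (negative means sicker participants cost more
#'   and score worse).
#' @param missing_rate_followup expected fraction of follow-up measurements
#'   masked (missing at random, depending on baseline severity only).
#' @param therapist_minutes_mean mean therapist time (minutes) logged per
#'   intervention-arm participant; 0 disables intervention costs.
#' @param therapist_minutes_cv coefficient of variation of therapist minutes.
#' @param seed integer seed; the generator is fully deterministic given it.
#'
#' @return A validated list of class `"trial_config"`.
#' @export
#' @examples
#' cfg <- trial_config(n_per_arm = 20, seed = 42)
#' trial <- generate_trial(cfg)
#' head(trial$weekly)
trial_config <- function(n_per_arm = 83,
                         weeks_of_weekly_obs = 17,
                         assessment_weeks = c(0, 16, 24),
                         baseline_nssi_weekly_mean = 2.8,
                         control_weekly_trend = 0.986,
                         irr_treatment_by_time = 0.966,
                         zero_inflation = 0.25,
                         nb_dispersion = 1.5,
                         random_effect_sd_intercept = 0.6,
                         random_effect_sd_slope = 0.02,
                         baseline_utility_mean = 0.632,
                         baseline_utility_sd = 0.04,
                         utility_effect = 0.03,
                         cost_means = default_cost_means(),
                         cost_outcome_corr = -0.3,
                         missing_rate_followup = 0.08,
                         therapist_minutes_mean = 1550,
                         therapist_minutes_cv = 0.25,
                         seed = 1L) {
  cfg <- list(n_per_arm = n_per_arm,
              weeks_of_weekly_obs = weeks_of_weekly_obs,
              assessment_weeks = assessment_weeks,
              baseline_nssi_weekly_mean = baseline_nssi_weekly_mean,
              control_weekly_trend = control_weekly_trend,
              irr_treatment_by_time = irr_treatment_by_time,
              zero_inflation = zero_inflation,
              nb_dispersion = nb_dispersion,
              random_effect_sd_intercept = random_effect_sd_intercept,
              random_effect_sd_slope = random_effect_sd_slope,
              baseline_utility_mean = baseline_utility_mean,
              baseline_utility_sd = baseline_utility_sd,
              utility_effect = utility_effect,
              cost_means = cost_means,
              cost_outcome_corr = cost_outcome_corr,
              missing_rate_followup = missing_rate_followup,
              therapist_minutes_mean = therapist_minutes_mean,
              therapist_minutes_cv = therapist_minutes_cv,
              seed = seed)
  validate_trial_config(cfg)
  class(cfg) <- "trial_config"
  cfg
}

#' Default expected resource-use quantities per 12-week recall period
#'
#' Calibration fixture: quantities per category chosen so that, priced with
#' the bundled illustrative unit-cost table, arm-level baseline cost summaries
#' are of the same order as published adolescent NSSI trial data (health care
#' roughly $4000, societal roughly $20,000 per 12 weeks). Equal in both arms.
#'
#' @return Named list of per-category expected quantities.
#' @export
default_cost_means <- function() {
  list(healthcare_visit_outpatient = 13,
       healthcare_visit_primary    = 4,
       medication                  = 6,
       supplement                  = 2,
       social_support              = 12,
       informal_support_hours      = 110,
       school_absence_days         = 18,
       school_presenteeism         = 45,
       parent_paid_absence_days    = 28,
       parent_unpaid_absence_hours = 100)
}

validate_trial_config <- function(cfg) {
  fail <- function(field, msg) stop(sprintf("invalid trial_config field '%s': %s",
                                            field, msg), call. = FALSE)
  if (!is.numeric(cfg$n_per_arm) || cfg$n_per_arm < 2 ||
      cfg$n_per_arm != round(cfg$n_per_arm))
    fail("n_per_arm", "must be an integer >= 2")
  if (!is.numeric(cfg$weeks_of_weekly_obs) || cfg$weeks_of_weekly_obs < 2)
    fail("weeks_of_weekly_obs", "must be >= 2")
  aw <- cfg$assessment_weeks
  if (length(aw) < 2 || aw[1] != 0 || any(diff(aw) <= 0))
    fail("assessment_weeks", "must be strictly increasing and start at 0")
  for (f in c("zero_inflation", "missing_rate_followup"))
    if (!is.numeric(cfg[[f]]) || is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      fail(f, "must be a probability in [0, 1]")
  for (f in c("nb_dispersion", "irr_treatment_by_time", "control_weekly_trend",
              "baseline_nssi_weekly_mean"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) fail(f, "must be positive")
  for (f in c("random_effect_sd_intercept", "random_effect_sd_slope",
              "baseline_utility_sd", "therapist_minutes_mean",
              "therapist_minutes_cv"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) fail(f, "must be nonnegative")
  if (!is.numeric(cfg$cost_outcome_corr) || abs(cfg$cost_outcome_corr) > 1)
    fail("cost_outcome_corr", "must lie in [-1, 1]")
  if (!is.list(cfg$cost_means) || is.null(names(cfg$cost_means)) ||
      any(!vapply(cfg$cost_means, function(x)
        is.numeric(x) && all(x > 0) && length(x) %in% c(1L, 2L), logical(1))))
    fail("cost_means", "must be a named list of positive scalars or length-2 vectors")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    fail("seed", "must be a single integer")
  invisible(cfg)
}

# Count-like categories whose simulated quantities are rounded to integers.
.count_categories <- c("healthcare_visit_outpatient", "healthcare_visit_primary",
                       "medication", "supplement", "school_absence_days",
                       "school_presenteeism", "parent_paid_absence_days")

#' Generate a complete synthetic trial
#'
#' Simulates participants, weekly NSSI counts, assessment-point outcomes,
#' resource use and therapist time with the statistical structure the
#' downstream analysis assumes: weekly counts follow a zero-inflated negative
#' binomial whose log-mean carries an arm-by-week interaction
#' `log(irr_treatment_by_time)` plus per-subject random intercept and slope;
#' utilities and log resource-use quantities share a latent severity factor
#' that induces the configured negative cost-outcome correlation; follow-up
#' measurements are masked missing-at-random via [mask_mar()].
#'
#' @param config a [trial_config()].
#' @return An object of class `"ce_trial"`: list with data frames
#'   `participants` (id, arm, age, sex, therapist_minutes), `weekly`
#'   (id, arm, week, nssi_count), `assessments` (id, arm, week, timepoint,
#'   kidscreen, past_month_nssi, instrument missingness flags),
#'   `resource_use` (id, period, category, quantity, percent_loss), plus the
#'   `config`. Masked cells are `NA` with their flag set.
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "trial_config")) config <- do.call(trial_config, config)
  validate_trial_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    n <- 2L * cfg$n_per_arm
    id <- sprintf("P%03d", seq_len(n))
    arm <- rep(c("intervention", "control"), each = cfg$n_per_arm)
    a <- as.integer(arm == "intervention")
    age <- round(stats::runif(n, 13, 17.99), 1)
    sex <- sample(c("female", "male", "nonbinary"), n, replace = TRUE,
                  prob = c(0.93, 0.04, 0.03))

    # latent severity and correlated random effects
    z <- stats::rnorm(n)                       # severity: high = sicker
    rho_b <- 0.6                               # severity share of the intercept RE
    b0 <- cfg$random_effect_sd_intercept *
      (rho_b * z + sqrt(1 - rho_b^2) * stats::rnorm(n))
    b1 <- cfg$random_effect_sd_slope * stats::rnorm(n)

    # weekly counts: ZINB, log-mean = log(mu0) + log(trend)*wk + a*log(irr)*wk + b0 + b1*wk
    mu0 <- cfg$baseline_nssi_weekly_mean / (1 - cfg$zero_inflation)
    wks <- 0:(cfg$weeks_of_weekly_obs - 1L)
    wk_grid <- rep(wks, times = n)
    id_grid <- rep(id, each = length(wks))
    a_grid <- rep(a, each = length(wks))
    eta <- log(mu0) - cfg$random_effect_sd_intercept^2 / 2 +
      rep(b0, each = length(wks)) + rep(b1, each = length(wks)) * wk_grid +
      log(cfg$control_weekly_trend) * wk_grid +
      a_grid * log(cfg$irr_treatment_by_time) * wk_grid
    struct_zero <- stats::runif(length(eta)) < cfg$zero_inflation
    counts <- ifelse(struct_zero, 0L,
                     stats::rnbinom(length(eta), size = cfg$nb_dispersion,
                                    mu = exp(eta)))
    weekly <- data.frame(id = id_grid, arm = rep(arm, each = length(wks)),
                         week = wk_grid, nssi_count = as.integer(counts),
                         stringsAsFactors = FALSE)

    # assessment-point past-month counts: 4x the weekly mean at that week
    aw <- cfg$assessment_weeks
    tp <- period_labels(aw)
    pm <- matrix(0L, n, length(aw))
    for (k in seq_along(aw)) {
      eta_k <- log(mu0) - cfg$random_effect_sd_intercept^2 / 2 + b0 + b1 * aw[k] +
        log(cfg$control_weekly_trend) * aw[k] +
        a * log(cfg$irr_treatment_by_time) * aw[k]
      sz <- stats::runif(n) < cfg$zero_inflation
      pm[, k] <- ifelse(sz, 0L,
                        stats::rnbinom(n, size = cfg$nb_dispersion,
                                       mu = 4 * exp(eta_k)))
    }

    # utilities share the severity factor; mapped to a KidScreen-like score
    w_u <- sqrt(abs(cfg$cost_outcome_corr)) * sign(cfg$cost_outcome_corr) *
      cfg$baseline_utility_sd
    util <- matrix(NA_real_, n, length(aw))
    util[, 1] <- cfg$baseline_utility_mean + w_u * z +
      sqrt(max(cfg$baseline_utility_sd^2 - w_u^2, 1e-8)) * stats::rnorm(n)
    ramp_wk <- if (length(aw) >= 2) aw[2] else 16
    for (k in seq_along(aw)[-1]) {
      gain <- 0.005 * min(aw[k] / ramp_wk, 1) +
        a * cfg$utility_effect * min(aw[k] / ramp_wk, 1)
      util[, k] <- util[, 1] + gain + 0.02 * stats::rnorm(n)
    }
    util <- pmin(pmax(util, 0.05), 0.98)
    map <- default_mapping_model()
    kidscreen <- round((util - map$intercept) / map$slope, 1)

    # resource use: log-normal quantities with severity loading, per period
    periods <- data.frame(period = tp, weeks = c(12, rep(NA, length(aw) - 1)),
                          stringsAsFactors = FALSE)
    periods$weeks[-1] <- pmin(diff(aw), 12)
    w_c <- 0.8 * abs(cfg$cost_outcome_corr)
    sdlog <- 0.7
    ru <- vector("list", length(tp) * length(cfg$cost_means))
    ix <- 0L
    for (p in seq_along(tp)) {
      scale_p <- periods$weeks[p] / 12
      for (cat in names(cfg$cost_means)) {
        m <- cfg$cost_means[[cat]]
        m_arm <- if (length(m) == 2L) m[1 + (1 - a)] else rep(m, n)
        meanlog <- log(m_arm * scale_p) - (sdlog^2 + w_c^2) / 2
        q <- exp(meanlog + w_c * z + sdlog * stats::rnorm(n))
        if (cat %in% .count_categories) q <- round(q)
        pl <- if (cat == "school_presenteeism")
          round(100 * stats::rbeta(n, 2.2, 1.8), 1) else rep(NA_real_, n)
        ix <- ix + 1L
        ru[[ix]] <- data.frame(id = id, period = tp[p], category = cat,
                               quantity = q, percent_loss = pl,
                               stringsAsFactors = FALSE)
      }
    }
    resource_use <- do.call(rbind, ru)
    resource_use <- resource_use[order(resource_use$id, resource_use$period,
                                       resource_use$category), ]
    rownames(resource_use) <- NULL

    tm_mean <- cfg$therapist_minutes_mean
    therapist <- if (tm_mean > 0) {
      sl <- sqrt(log(1 + cfg$therapist_minutes_cv^2))
      a * exp(log(tm_mean) - sl^2 / 2 + sl * stats::rnorm(n))
    } else rep(0, n)

    assessments <- data.frame(
      id = rep(id, times = length(aw)),
      arm = rep(arm, times = length(aw)),
      week = rep(aw, each = n),
      timepoint = rep(tp, each = n),
      kidscreen = as.vector(kidscreen),
      past_month_nssi = as.integer(pm),
      kidscreen_missing = FALSE, dshi_missing = FALSE, ticp_missing = FALSE,
      stringsAsFactors = FALSE)
    assessments <- assessments[order(assessments$id, assessments$week), ]
    rownames(assessments) <- NULL

    trial <- structure(list(
      participants = data.frame(id = id, arm = arm, age = age, sex = sex,
                                therapist_minutes = therapist,
                                stringsAsFactors = FALSE),
      weekly = weekly, assessments = assessments, resource_use = resource_use,
      config = cfg), class = "ce_trial")

    mask_mar(trial, rate = cfg$missing_rate_followup,
             seed = substream_seed(cfg$seed, 1L))
  })
}

period_labels <- function(assessment_weeks) {
  k <- length(assessment_weeks)
  lab <- c("baseline", "post1m", "post3m")
  if (k <= 3) lab[seq_len(k)] else c(lab, paste0("fu", seq_len(k - 3)))
}

#' Mask follow-up measurements missing-at-random
#'
#' Masks follow-up assessment values (clinician-rated past-month NSSI,
#' KidScreen score, and the resource-use block of the matching recall period)
#' with a per-participant probability that averages `rate` but varies with the
#' participant's observed baseline severity (rank of baseline past-month NSSI
#' minus standardized baseline KidScreen). Baseline is never masked, matching
#' trials where all participants complete the baseline assessment, and the
#' mechanism depends on observed baseline data only (MAR).
#'
#' @param trial a `"ce_trial"` object.
#' @param rate target average masking probability in [0, 1].
#' @param seed integer seed; masking is reproducible given it.
#' @return The trial with masked cells set to `NA` and flags updated.
#' @export
mask_mar <- function(trial, rate, seed = 1L) {
  stopifnot(inherits(trial, "ce_trial"))
  assert_prob(rate, "rate")
  if (rate == 0) return(trial)
  asm <- trial$assessments
  base <- asm[asm$timepoint == "baseline", ]
  base <- base[match(trial$participants$id, base$id), ]
  sev <- rank(base$past_month_nssi, ties.method = "average") -
    rank(base$kidscreen, ties.method = "average")
  q <- (rank(sev, ties.method = "first") - 0.5) / nrow(base)
  p_i <- pmin(pmax(rate + 1.2 * rate * (1 - rate) * (q - 0.5), 0), 1)
  names(p_i) <- base$id

  with_seed(seed, {
    fu <- which(asm$timepoint != "baseline")
    p_row <- p_i[asm$id[fu]]
    for (ins in c("dshi", "kidscreen", "ticp")) {
      hit <- stats::runif(length(fu)) < p_row
      col <- paste0(ins, "_missing")
      asm[[col]][fu][hit] <- TRUE
    }
    asm$past_month_nssi[asm$dshi_missing] <- NA_integer_
    asm$kidscreen[asm$kidscreen_missing] <- NA_real_
    trial$assessments <- asm
    # resource use of a masked TIC-P block becomes NA for that period
    masked <- asm[asm$ticp_missing, c("id", "timepoint")]
    if (nrow(masked)) {
      key <- paste(trial$resource_use$id, trial$resource_use$period)
      hit <- key %in% paste(masked$id, masked$timepoint)
      trial$resource_use$quantity[hit] <- NA_real_
    }
    trial
  })
}

#' Write a synthetic trial to CSV files
#'
#' Emits `participants.csv`, `weekly.csv`, `assessments.csv`,
#' `resource_use.csv` and a `config.json` (including the seed) into `dir`.
#'
#' @param trial a `"ce_trial"` object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "ce_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("participants", "weekly", "assessments", "resource_use")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(trial[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  cfgp <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(trial$config), cfgp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, cfgp))
}
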