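# Shared fixtures, built in code.

tiny_cost_table <- function() {
  unit_cost_table(
    unit_costs = list(healthcare_visit_outpatient = 200, medication = 50,
                      supplement = 20, social_support = 100),
    daily_salary_plus_social_fees = 300,
    posttax_hourly_wage = 15,
    annual_cost_per_pupil = 9000,   # 50 per school day
    school_days_per_year = 180,
    psychologist_hourly_cost = 100)
}

identity_basis <- function() price_basis(c("2022" = 100), 2022, 2022, 1)

fixture_basis <- function() price_basis(c("2018" = 330.72, "2022" = 363.31),
                                        2018, 2022, 8.77)

# small complete analysis dataset with a known arm effect
toy_analysis_data <- function(n_per_arm = 30, cost_effect = 100,
                              qaly_effect = 0.01, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_arm
    arm <- rep(c("intervention", "control"), each = n_per_arm)
    a <- as.numeric(arm == "intervention")
    base_cost <- rlnorm(n, log(1000), 0.4)
    data.frame(
      id = sprintf("S%03d", 1:n), arm = arm,
      COST_baseline = base_cost,
      COST_post1m = 0.5 * base_cost + cost_effect * a + rlnorm(n, log(500), 0.4),
      utility_baseline = rnorm(n, 0.63, 0.04),
      qaly_post1m = rnorm(n, 0.19, 0.01) + qaly_effect * a,
      stringsAsFactors = FALSE)
  })
}

# independent per-record pricing, written as plain arithmetic (oracle)
brute_force_item_cost <- function(rec, tab) {
  per_day <- tab$annual_cost_per_pupil / tab$school_days_per_year
  switch(rec$category,
         school_presenteeism = rec$quantity * rec$percent_loss / 100 * per_day,
         school_absence_days = rec$quantity * per_day,
         parent_paid_absence_days = rec$quantity * tab$daily_salary_plus_social_fees,
         informal_support_hours = ,
         parent_unpaid_absence_hours = rec$quantity * tab$posttax_hourly_wage,
         rec$quantity * tab$unit_costs[[rec$category]])
}
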