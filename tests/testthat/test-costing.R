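test_that("uprating follows the CPI ratio and rejects bad input", {
  b <- fixture_basis()
  expect_equal(uprate(100, b), 100 * 363.31 / 330.72)
  expect_equal(uprate(100, identity_basis()), 100)
  expect_error(uprate(-5, b), "nonnegative")
  expect_error(price_basis(c("2018" = 330.72), 2018, 2022, 8.77), "2022")
})

test_that("PPP conversion divides by the rate", {
  b <- fixture_basis()
  expect_equal(to_usd(877, price_basis(c("2022" = 1), 2022, 2022, 8.77)), 100)
  expect_equal(to_usd(0, b), 0)
  expect_equal(to_usd(8.77, price_basis(c("2022" = 1), 2022, 2022, 8.77)), 1)
  expect_error(price_basis(c("2022" = 1), 2022, 2022, -1), "ppp_rate")
})

test_that("per-item pricing applies the category-specific formulas", {
  tab <- tiny_cost_table()
  expect_equal(cost_item(list(category = "healthcare_visit_outpatient",
                              quantity = 3), tab), 600)
  expect_equal(cost_item(list(category = "school_presenteeism", quantity = 10,
                              percent_loss = 40), tab), 200)
  expect_equal(cost_item(list(category = "parent_paid_absence_days",
                              quantity = 2), tab), 600)
  expect_equal(cost_item(list(category = "school_absence_days",
                              quantity = 4), tab), 200)
  expect_equal(cost_item(list(category = "informal_support_hours",
                              quantity = 10), tab), 150)
  expect_error(cost_item(list(category = "crystal_healing", quantity = 1), tab),
               "unpriced")
  expect_error(cost_item(list(category = "medication", quantity = -1), tab),
               "negative")
  expect_error(cost_item(list(category = "school_presenteeism", quantity = 1),
                         tab), "percent_loss")
})

test_that("intervention cost is therapist hours times the psychologist rate", {
  tab <- tiny_cost_table()
  expect_equal(intervention_cost(60, tab), 100)
  expect_equal(intervention_cost(0, tab), 0)
  expect_equal(intervention_cost(90, tab), 150)
  expect_error(intervention_cost(-1, tab), "negative")
})

test_that("aggregation separates perspectives and handles empties", {
  tab <- tiny_cost_table(); b <- identity_basis()
  rec <- data.frame(id = "P1", period = "post1m",
                    category = c("healthcare_visit_outpatient",
                                 "school_presenteeism"),
                    quantity = c(3, 10), percent_loss = c(NA, 40),
                    stringsAsFactors = FALSE)
  hc <- aggregate_costs(rec, tab, b, "healthcare")
  so <- aggregate_costs(rec, tab, b, "societal")
  expect_equal(hc$total, 600)
  expect_equal(so$total, 800)
  empty <- aggregate_costs(rec[0, ], tab, b, "societal")
  expect_equal(nrow(empty), 0)
  bad <- rec; bad$period <- "week99"
  expect_error(aggregate_costs(bad, tab, b, "societal"), "period")
})

test_that("aggregate totals equal a brute-force per-item summation", {
  tab <- tiny_cost_table(); b <- fixture_basis()
  set.seed(14)
  cats <- c("healthcare_visit_outpatient", "medication", "supplement",
            "social_support", "informal_support_hours", "school_absence_days",
            "school_presenteeism", "parent_paid_absence_days",
            "parent_unpaid_absence_hours")
  rec <- data.frame(id = sample(sprintf("P%d", 1:6), 50, TRUE),
                    period = sample(c("baseline", "post1m", "post3m"), 50, TRUE),
                    category = sample(cats, 50, TRUE),
                    quantity = round(runif(50, 0, 20), 1),
                    stringsAsFactors = FALSE)
  rec$percent_loss <- ifelse(rec$category == "school_presenteeism",
                             round(runif(50, 0, 100), 1), NA)
  agg <- aggregate_costs(rec, tab, b, "societal")
  fx <- b$cpi[["2022"]] / b$cpi[["2018"]] / b$ppp_rate
  for (r in sample(nrow(agg), 8)) {
    sub <- rec[rec$id == agg$id[r] & rec$period == agg$period[r], ]
    manual <- 0
    for (j in seq_len(nrow(sub)))
      manual <- manual + brute_force_item_cost(sub[j, ], tab) * fx
    expect_equal(agg$total[r], manual)
  }
  # total equals the sum of its per-category breakdown
  cats_present <- setdiff(names(agg), c("id", "period", "perspective", "total"))
  expect_equal(agg$total, rowSums(agg[, cats_present, drop = FALSE]))
})

test_that("societal totals dominate healthcare totals for every participant-period", {
  cc <- load_cost_config()
  trial <- generate_trial(trial_config(n_per_arm = 30, seed = 6))
  hc <- aggregate_costs(trial$resource_use, cc$table, cc$basis, "healthcare",
                        participants = trial$participants)
  so <- aggregate_costs(trial$resource_use, cc$table, cc$basis, "societal",
                        participants = trial$participants)
  key <- paste(hc$id, hc$period)
  so_tot <- so$total[match(key, paste(so$id, so$period))]
  both <- !is.na(so_tot) & !is.na(hc$total)
  expect_true(all(so_tot[both] >= hc$total[both]))
})

test_that("uprate and PPP conversion commute", {
  b <- fixture_basis()
  expect_equal(to_usd(uprate(123.45, b), b), uprate(to_usd(123.45, b), b))
})

test_that("accumulated 3-month totals are exactly additive over periods", {
  cc <- load_cost_config()
  trial <- generate_trial(trial_config(n_per_arm = 15, missing_rate_followup = 0,
                                       seed = 10))
  agg <- aggregate_costs(trial$resource_use, cc$table, cc$basis, "societal",
                         participants = trial$participants)
  acc <- accumulate_costs(agg)
  p1 <- agg$total[agg$period == "post1m"][match(acc$id,
                                                agg$id[agg$period == "post1m"])]
  p3 <- agg$total[agg$period == "post3m"][match(acc$id,
                                                agg$id[agg$period == "post3m"])]
  expect_equal(acc$accum_post3m, p1 + p3)
  expect_equal(acc$accum_post1m, p1)
  # baseline never enters the accumulations
  expect_equal(acc$accum_post1m + acc$baseline - acc$baseline, acc$accum_post1m)
})
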