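test_that("adjusted differences recover the arm coefficient", {
  d <- toy_analysis_data(10)
  d$y <- 5 * (d$arm == "intervention") + 1
  expect_equal(adjusted_diff(d, "y")$delta, 5)
  # algebra oracle: matches lm() with and without baseline adjustment
  fit <- lm(COST_post1m ~ I(arm == "intervention") + COST_baseline, data = d)
  expect_equal(adjusted_diff(d, "COST_post1m", baseline = "COST_baseline")$delta,
               unname(coef(fit)[2]))
  # balanced baselines: adjusted equals the raw mean difference
  db <- data.frame(arm = rep(c("intervention", "control"), each = 5),
                   y = c(3, 4, 5, 6, 7, 1, 2, 3, 4, 5),
                   x = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  expect_equal(adjusted_diff(db, "y", baseline = "x")$delta,
               mean(db$y[1:5]) - mean(db$y[6:10]))
  expect_error(adjusted_diff(db[c(1, 6:10), ], "y"), "per arm")
  db$z <- 2 * as.numeric(db$arm == "intervention")
  expect_error(adjusted_diff(db, "y", baseline = "z"), "collinear")
})

test_that("bootstrap draws are degenerate on constant data and deterministic under seed", {
  d <- toy_analysis_data(8)
  d$COST_post1m <- ifelse(d$arm == "intervention", 300, 100)
  d$qaly_post1m <- ifelse(d$arm == "intervention", 0.21, 0.20)
  spec <- outcome_spec("qaly", "COST_post1m", "qaly_post1m")
  dr <- bootstrap_cea(list(d), spec, B = 50, seed = 2)
  expect_true(all(dr$dC == 200))
  expect_true(all(abs(dr$dE - 0.01) < 1e-12))
  d2 <- toy_analysis_data(8)
  a1 <- bootstrap_cea(list(d2), spec, B = 30, seed = 9)
  a2 <- bootstrap_cea(list(d2), spec, B = 30, seed = 9)
  expect_identical(a1, a2)
  expect_false(identical(a1$dC,
                         bootstrap_cea(list(d2), spec, B = 30, seed = 10)$dC))
})

test_that("the effect direction flips for episodes-averted outcomes", {
  d <- toy_analysis_data(8)
  d$nssi <- ifelse(d$arm == "intervention", 2, 5)   # fewer episodes = better
  spec <- outcome_spec("nssi", "COST_post1m", "nssi", direction = -1)
  dr <- bootstrap_cea(list(d), spec, B = 5, seed = 1)
  expect_equal(attr(dr, "points")$dE, 3)   # control minus intervention
})

test_that("pooling combines Rubin means with stacked percentile intervals", {
  d <- toy_analysis_data(25, seed = 2)
  spec <- outcome_spec("qaly", "COST_post1m", "qaly_post1m",
                       baseline_cost = "COST_baseline",
                       baseline_effect = "utility_baseline")
  one <- pool_cea(bootstrap_cea(list(d), spec, B = 200, seed = 3))
  expect_equal(one$M, 1)
  # M identical imputations reproduce the single-dataset result
  thrice <- pool_cea(bootstrap_cea(list(d, d, d), spec, B = 200, seed = 3))
  expect_equal(thrice$dC, one$dC)
  expect_equal(thrice$dE, one$dE)
  expect_lte(one$ci_dC[1], one$dC); expect_gte(one$ci_dC[2], one$dC)
  # stacked-draw variance >= average within-imputation variance when imputations differ
  d2 <- d; d2$COST_post1m <- d2$COST_post1m * 1.5
  dr <- bootstrap_cea(list(d, d2), spec, B = 300, seed = 5)
  within_var <- mean(tapply(dr$dC, dr$imputation, var))
  expect_gte(var(dr$dC), within_var)
})

test_that("ICER arithmetic and context flags", {
  expect_equal(as.numeric(icer(100, 0.5)), 200)
  dom <- icer(-50, 0.5)
  expect_equal(as.numeric(dom), -100)
  expect_match(attr(dom, "context"), "dominant")
  expect_equal(as.numeric(icer(4458, 0.005)), 891600)
  expect_match(attr(icer(4458, 0.005), "context"), "northeast")
  expect_error(icer(10, 0), "undefined")
})

test_that("net monetary benefit is linear in willingness to pay", {
  expect_equal(nmb(84000, 4458, 0.005), -4038)
  expect_equal(nmb(0, 4458, 0.005), -4458)
  expect_equal(nmb(c(1000, 2000), 0, 0), c(0, 0))
  expect_equal(nmb(5000, 100, 0), -100)
  expect_error(nmb(-1, 0, 0), "negative")
  lam <- seq(0, 1e5, length.out = 11)
  out <- nmb(lam, 250, 0.004)
  expect_equal(diff(out), rep(0.004 * diff(lam)[1], 10))
})

test_that("CEAC matches brute-force counting and obeys its limits", {
  set.seed(60)
  dr <- structure(data.frame(dC = rnorm(1000, 50, 100),
                             dE = rnorm(1000, 0.002, 0.01)),
                  class = c("ce_draws", "data.frame"))
  lam <- seq(0, 50000, by = 2500)
  cv <- ceac(dr, lam)
  for (i in seq_along(lam))
    expect_equal(cv$prob_ce[i], sum(lam[i] * dr$dE - dr$dC > 0) / 1000)
  expect_equal(ceac(dr, 0)$prob_ce, mean(dr$dC < 0))
  expect_equal(ceac(dr, 1e12)$prob_ce,
               mean(dr$dE > 0 | (dr$dE == 0 & dr$dC < 0)))
  # monotone when every draw has nonnegative incremental effect
  dr_pos <- dr; dr_pos$dE <- abs(dr_pos$dE)
  expect_true(all(diff(ceac(dr_pos, lam)$prob_ce) >= 0))
  # all dominant draws
  dr_dom <- dr; dr_dom$dC <- -abs(dr_dom$dC); dr_dom$dE <- abs(dr_dom$dE) + 1e-9
  expect_true(all(ceac(dr_dom, lam)$prob_ce == 1))
  single <- structure(data.frame(dC = 100, dE = 0.01),
                      class = c("ce_draws", "data.frame"))
  expect_equal(ceac(single, c(9999, 10001))$prob_ce, c(0, 1))
  expect_error(ceac(dr[0, ], lam), "empty")
})

test_that("plane quadrants classify signs with the axis tie rule", {
  allpp <- structure(data.frame(dC = c(1, 2), dE = c(0.1, 0.2)),
                     class = c("ce_draws", "data.frame"))
  expect_equal(ce_plane(allpp)$proportions[["NE"]], 1)
  ties <- structure(data.frame(dC = c(0, 5, -5), dE = c(0.1, 0, 0)),
                    class = c("ce_draws", "data.frame"))
  pr <- ce_plane(ties)$proportions
  expect_equal(pr[["NE"]], 2 / 3)   # dE=0 counts east, dC=0 counts north
  expect_equal(pr[["SE"]], 1 / 3)
  expect_equal(sum(pr), 1)
  set.seed(61)
  sym <- structure(data.frame(dC = rnorm(20000), dE = rnorm(20000)),
                   class = c("ce_draws", "data.frame"))
  expect_true(all(abs(ce_plane(sym)$proportions - 0.25) < 0.02))
})
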