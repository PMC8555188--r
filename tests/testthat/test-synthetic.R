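test_that("the synthetic ledger has the two-area 54-observation shape", {
  lg <- generate_ledger(seed = 5)
  am <- unique(lg[c("month", "area")])
  expect_equal(nrow(am), 54)
  expect_equal(sum(am$area == 1), 31)
  expect_equal(sum(am$area == 2), 23)
  # area 2 spans the final 23 calendar months
  expect_equal(sort(unique(lg$month[lg$area == 2])), 9:31)
  expect_equal(nrow(lg), 54 * nrow(default_cost_params()))
  # seeded reproducibility
  expect_identical(generate_ledger(seed = 5), lg)
  expect_false(identical(generate_ledger(seed = 6), lg))
})

test_that("generated program-month series respect bounds and match means", {
  lg <- generate_ledger(seed = 12)
  cp <- default_cost_params()
  for (i in seq_len(nrow(cp))) {
    tot <- tapply(lg$amount[lg$category == cp$category[i]],
                  lg$month[lg$category == cp$category[i]], sum)
    expect_true(all(tot >= cp$monthly_min[i] - 1e-8 &
                      tot <= cp$monthly_max[i] + 1e-8))
  }
  wages <- tapply(lg$amount[lg$category == "wages_field"],
                  lg$month[lg$category == "wages_field"], sum)
  expect_equal(mean(wages), 45051, tolerance = 0.10)
  # enrollment ramps up and stays inside the published range
  am <- lg[!duplicated(lg[c("month", "area")]), ]
  enr <- tapply(am$enrollment, am$month, sum)
  expect_true(all(enr >= 1664 & enr <= 47992))
  expect_true(enr[1] < 0.25 * max(enr))
})

test_that("zero-SD moments give a constant ledger and infeasible ones error", {
  m <- ledger_moments()
  m$costs$monthly_sd[] <- 0
  m$costs$monthly_min <- m$costs$monthly_max <- m$costs$monthly_mean
  lg <- generate_ledger(m, seed = 1, noise_cv = 0)
  for (cc in unique(lg$category)) {
    tot <- tapply(lg$amount[lg$category == cc], lg$month[lg$category == cc],
                  sum)
    expect_equal(unname(diff(range(tot))), 0)
  }
  bad <- ledger_moments()
  bad$costs$monthly_max[5] <- bad$costs$monthly_mean[5] / 2
  expect_error(generate_ledger(bad, seed = 1), "infeasible")
})

test_that("the synthetic ledger closes the costing pipeline", {
  lg <- generate_ledger(seed = 99)
  s <- build_annual_summary(lg)
  expect_equal(s$total, 647074, tolerance = 0.15)
  expect_true(s$cost_per_child > 0)
  # and feeds a full CEA re-run through the ledger-derived summary
  cfg <- cea_config(caseload = s$caseload, n_creches = s$n_creches)
  cfg$costs$params$annual <- s$categories$annual[
    match(cfg$costs$params$category, s$categories$category)]
  fit <- creche_cea(cfg)
  expect_true(is.finite(fit$point$icer_life_program))
})

test_that("microsimulated cohorts behave at the degenerate corners", {
  b0 <- default_age_bands()
  b0$sq_incidence[] <- 0
  b0$cr_incidence[] <- 0
  out0 <- generate_cohort_outcomes(sim_cohort_config(2e4, b0, seed = 1))
  expect_equal(sum(out0$died), 0)
  # null scenario: both arms share the status-quo incidences
  bn <- default_age_bands()
  bn$cr_incidence <- bn$sq_incidence
  outn <- generate_cohort_outcomes(sim_cohort_config(2e5, bn, seed = 2))
  # three binomial SEs of the null difference at this sample size
  se_null <- sqrt(2 * 111e-5 / 2e5) * 1e5
  expect_lt(abs(estimate_lives_saved(outn)), 3 * se_null)
  # attendance tiers only occur for attenders
  expect_true(all((outn$tier == "none") == !outn$attended))
})

test_that("the wage proxy series is a seeded stand-in", {
  w1 <- generate_wage_proxy(seed = 8)
  expect_length(w1, 10)
  expect_identical(w1, generate_wage_proxy(seed = 8))
  w <- generate_wage_proxy(n = 5000, seed = 9)
  expect_equal(mean(w), 78.48, tolerance = 0.02)
  expect_equal(sd(w), 16.49, tolerance = 0.05)
})
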