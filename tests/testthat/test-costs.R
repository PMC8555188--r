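test_that("fixed-cost annualization follows the annuity closed form", {
  expect_equal(annualize_fixed(1000, 10, 0.03), 117.23, tolerance = 1e-4)
  expect_equal(annualize_fixed(1000, 1, 0.03), 1030.00)
  expect_equal(annualize_fixed(1000, 10, 0), 100.00)
  expect_error(annualize_fixed(1000, 0, 0.03), "positive")
  # round trip through the annuity factor
  set.seed(41)
  for (i in 1:8) {
    x <- runif(1, 10, 1e5); life <- runif(1, 0.5, 20)
    r <- runif(1, 0, 0.1)
    expect_equal(annualize_fixed(x, life, r) * annuity_factor(life, r), x)
  }
})

test_that("ledger normalization applies deflator, fx and effort", {
  lg <- data.frame(month = 1, area = 1, category = "wages_field",
                   amount = 100, year = 2014)
  out <- normalize_ledger(lg, deflator = c("2014" = 1.06), fx = 0.01282)
  expect_equal(out$amount, 1.36, tolerance = 0.004)
  # zero effort removes the cost; unit factors are the identity
  lg$effort <- 0
  expect_equal(normalize_ledger(lg)$amount, 0)
  lg$effort <- 1
  expect_equal(normalize_ledger(lg)$amount, 100)
  # a missing deflator year is named in the error
  lg$year <- 2012
  expect_error(normalize_ledger(lg, deflator = c("2014" = 1.06)), "2012")
  expect_error(normalize_ledger(transform(lg, effort = 1.2)), "\\[0, 1\\]")
})

test_that("published category totals reproduce the annual cost table", {
  s <- annual_summary_from_totals(table2_totals(), caseload = 40378,
                                  n_creches = 1554)
  expect_equal(s$fixed_subtotal, 45896, tolerance = 1 / 45896)
  expect_equal(s$variable_subtotal, 601179, tolerance = 2 / 601179)
  expect_equal(s$total, 647074, tolerance = 2 / 647074)
  expect_equal(s$cost_per_child, 16.03, tolerance = 0.01 / 16)
  expect_equal(s$cost_per_creche, 416.35, tolerance = 5e-4)
  # conservation: total equals the category-level outputs
  expect_equal(s$total, sum(s$categories$annual))
})

test_that("average costs are homogeneous in amounts and monotone in caseload", {
  tot <- table2_totals()
  s1 <- annual_summary_from_totals(tot, 40378, 1554)
  s2 <- annual_summary_from_totals(3 * tot, 40378, 1554)
  expect_equal(s2$total, 3 * s1$total)
  expect_equal(s2$cost_per_child, 3 * s1$cost_per_child)
  expect_equal(s2$cost_per_creche, 3 * s1$cost_per_creche)
  cl <- seq(2e4, 6e4, length.out = 5)
  pc <- vapply(cl, function(x)
    annual_summary_from_totals(tot, x, 1554)$cost_per_child, numeric(1))
  expect_true(all(diff(pc) < 0))
  expect_error(annual_summary_from_totals(tot, 0, 1554), "positive")
})

test_that("ledger-based summary uses the capacity-month run rate", {
  lg <- constant_ledger(n_months = 10, wages = 1000, transport = 100,
                        enrollment = 500)
  # two ramp-up months: low enrollment, inflated spending
  lg$enrollment[lg$month <= 2] <- 100
  lg$amount[lg$month <= 2 & lg$category == "wages_field"] <- 5000
  s <- build_annual_summary(lg)
  expect_equal(s$categories$annual[s$categories$category == "wages_field"],
               12 * 1000)
  expect_equal(s$caseload, 500)
  expect_equal(s$total, 12 * 1100)
  expect_error(build_annual_summary(lg[0, ]), "empty")
})

test_that("fixed categories can be annualized from raw investments", {
  lg <- constant_ledger(n_months = 12, wages = 0, transport = 0)
  lg <- rbind(lg, data.frame(month = 1, area = 1, category = "equipment",
                             amount = 1200, enrollment = 500, creches = 20))
  s <- build_annual_summary(lg, fixed_as_investment = TRUE)
  eq <- s$categories$annual[s$categories$category == "equipment"]
  expect_equal(eq, annualize_fixed(1200, 7.5, 0.03))
})

test_that("monthly trend conserves totals and flags start-up months", {
  lg <- constant_ledger(n_months = 4)
  tr <- monthly_trend(lg)
  expect_equal(nrow(tr), 4)
  expect_true(all(tr$total == tr$total[1]))     # flat trend
  expect_true(!any(tr$startup))
  # a 31-month ledger: one point per month, totals conserved
  lg31 <- constant_ledger(n_months = 31)
  lg31$amount <- runif(nrow(lg31), 10, 100)
  lg31$enrollment <- round(seq(50, 1000, length.out = 31))[lg31$month]
  tr31 <- monthly_trend(lg31)
  expect_equal(nrow(tr31), 31)
  expect_equal(sum(tr31$total), sum(lg31$amount))
  expect_equal(tr31$startup, tr31$enrollment < 0.5 * max(tr31$enrollment))
  expect_error(monthly_trend(constant_ledger(n_months = 1)), "two months")
})
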