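test_that("the default configuration validates with no errors", {
  v <- validate_config(cea_config())
  expect_equal(sum(v$severity == "error"), 0)
  # the published 12-23-month lives-saved CI oddity is surfaced as a note
  expect_true(any(v$severity == "note" & v$field == "ls_ci"))
})

test_that("invariant violations are reported as data naming the field", {
  cfg <- cea_config()
  cfg$effectiveness$bands$sq_ci_low[1] <- 500  # low > high
  v <- validate_config(cfg)
  expect_true(any(v$severity == "error" & grepl("sq_ci", v$field)))
  cfg2 <- cea_config()
  cfg2$costs$params$useful_life[1] <- -2
  v2 <- validate_config(cfg2)
  expect_true(any(v2$severity == "error" & grepl("useful_life", v2$field)))
  expect_error(creche_cea(cfg2), "useful_life")
})

test_that("a zero-effect configuration aborts with an undefined ICER", {
  cfg <- cea_config()
  cfg$effectiveness$bands$cr_incidence <- cfg$effectiveness$bands$sq_incidence
  cfg$effectiveness$bands$cr_ci_low <- cfg$effectiveness$bands$sq_ci_low
  cfg$effectiveness$bands$cr_ci_high <- cfg$effectiveness$bands$sq_ci_high
  expect_error(creche_cea(cfg), "undefined")
})

test_that("doubling the wage doubles societal savings, not the program ICER", {
  base <- creche_cea()
  cfg <- cea_config(societal = societal_params(min_monthly_wage = 2 * 78.48))
  dbl <- creche_cea(cfg)
  expect_equal(dbl$point$icer_life_program, base$point$icer_life_program)
  expect_equal(dbl$societal$worker_time, 2 * base$societal$worker_time)
  expect_equal(dbl$societal$parent_time, 2 * base$societal$parent_time)
})

test_that("the deterministic run is idempotent and byte-reproducible", {
  f1 <- creche_cea()
  f2 <- creche_cea()
  expect_identical(f1$point, f2$point)
  d1 <- file.path(tempdir(), "cea_out1")
  d2 <- file.path(tempdir(), "cea_out2")
  run_full_analysis(out_dir = d1)
  run_full_analysis(out_dir = d2)
  files <- c("cohort_deaths.tsv", "lives_saved.tsv", "program_costs.tsv",
             "societal_costs.tsv", "icers.tsv", "summary.txt")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  ic <- read.delim(file.path(d1, "icers.tsv"))
  expect_equal(nrow(ic), 6)
})

test_that("model methods expose coefficients, predictions and simulations", {
  fit <- creche_cea()
  cf <- coef(fit)
  expect_equal(unname(cf["cost_per_child"]), fit$costs$cost_per_child)
  expect_output(print(fit), "ICERs")
  expect_output(print(summary(fit)), "Societal cost per child")
  # predict() agrees with the sweep machinery
  pr <- predict(fit, newdata = list(lives_saved = 0.8 * fit$effect$lives_saved))
  sw <- proportional_sweep(fit, "lives_saved", multipliers = 0.8)
  expect_equal(pr$icer_life_program, sw$outcome[sw$multiplier == 0.8])
  expect_error(predict(fit, newdata = list(bogus = 1)), "unknown")
  expect_identical(predict(fit), fit$point)
  sim <- simulate(fit, nsim = 200, seed = 3)
  expect_equal(nrow(sim), 200)
  expect_s3_class(attr(sim, "psa"), "psa_result")
  # plots render without error onto a null device
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(fit, "sweep"))
  expect_no_error(plot(fit, "tornado"))
})
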