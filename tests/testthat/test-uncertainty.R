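test_that("distribution fitting recovers the generating family", {
  set.seed(101)
  x <- rnorm(54, 100, 10)
  f <- fit_input(x)
  expect_equal(f$family, "norm")
  expect_equal(f$params[1], 100, tolerance = 0.15)
  expect_equal(f$params[2], 10, tolerance = 0.15)
  expect_equal(f$truncation, range(x))
  # strongly skewed data: lognormal beats the normal on AIC
  set.seed(102)
  y <- rlnorm(54, 3, 1)
  fy <- fit_input(y, families = c("norm", "lnorm"))
  expect_equal(fy$family, "lnorm")
  # degenerate series collapse to a point mass
  fz <- fit_input(rep(7, 10))
  expect_equal(fz$family, "point")
  expect_equal(draw_input(fz, 5), rep(7, 5))
  expect_error(fit_input(1:3), "at least 5")
})

test_that("effect distribution moment-matches the lives-saved estimate", {
  ed <- effect_distribution(95.41, c(70.60, 101.36))
  expect_equal(ed$family, "lnorm")
  # SD identical to the CI formula used everywhere else
  s <- sd_from_ci(70.60, 101.36)
  expect_equal(sqrt((exp(ed$params[2]^2) - 1)) * ed$target_mean, s,
               tolerance = 1e-10)
  # analytic arithmetic mean of the fitted lognormal
  expect_equal(exp(ed$params[1] + ed$params[2]^2 / 2), 95.41,
               tolerance = 0.001)
  expect_equal(effect_distribution(95.41, c(95.41, 95.41))$family, "point")
})

test_that("recentered truncated draws respect bounds and the target mean", {
  # the published wage moments: mean far above the window midpoint
  fi <- fitted_input("wages_field", "norm", c(45051, 16329), c(687, 50825),
                     target_mean = 45051)
  set.seed(103)
  d <- draw_input(fi, 2e5)
  expect_true(all(d >= 687 & d <= 50825))
  expect_equal(mean(d), 45051, tolerance = 0.02)
  # positivity-preserving scale recentering for a gamma input
  fg <- fitted_input("g", "gamma", c(4, 2), c(0.5, 10), target_mean = 3)
  set.seed(104)
  dg <- draw_input(fg, 2e5)
  expect_true(all(dg >= 0.5 & dg <= 10))
  expect_equal(mean(dg), 3, tolerance = 0.02)
  expect_error(fitted_input("bad", "norm", c(5, 1), c(0, 1),
                            target_mean = 5), "outside truncation")
})

test_that("the PSA is seed-deterministic and collapses under point inputs", {
  fit <- creche_cea()
  p1 <- run_psa(fit, n = 2000, seed = 42)
  p2 <- run_psa(fit, n = 2000, seed = 42)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$ci, p2$ci)
  # all-degenerate inputs: the interval collapses onto the point estimate
  degen <- lapply(names(default_psa_inputs(fit)), function(nm) {
    b <- fit$baseline[[nm]]
    fitted_input(nm, "point", b, c(b, b), b)
  })
  pd <- run_psa(fit, n = 50, seed = 1, inputs = degen)
  row <- pd$ci[pd$ci$outcome == "icer_life_program", ]
  expect_equal(row$lo, fit$point$icer_life_program, tolerance = 1e-10)
  expect_equal(row$hi, fit$point$icer_life_program, tolerance = 1e-10)
})

test_that("PSA intervals bracket the point ICER and widen with input CV", {
  fit <- creche_cea()
  mk <- function(cv) {
    nms <- c(fit$baseline$cost_categories, "lives_saved", "min_wage",
             "children_per_creche")
    lapply(setNames(nm = nms), function(nm) {
      b <- fit$baseline[[nm]]
      if (b == 0) return(fitted_input(nm, "point", b, c(b, b), b))
      fitted_input(nm, "norm", c(b, cv * b), b * c(0.2, 2.5),
                   target_mean = b)
    })
  }
  p10 <- run_psa(fit, n = 20000, seed = 7, inputs = mk(0.10))
  p20 <- run_psa(fit, n = 20000, seed = 7, inputs = mk(0.20))
  for (p in list(p10, p20)) {
    row <- p$ci[p$ci$outcome == "icer_life_program", ]
    expect_true(row$lo < fit$point$icer_life_program &&
                  fit$point$icer_life_program < row$hi)
  }
  w <- function(p) {
    row <- p$ci[p$ci$outcome == "icer_life_program", ]
    row$hi - row$lo
  }
  expect_true(w(p20) > w(p10))
})

test_that("tornado ranks inputs and is symmetric for linear cost inputs", {
  fit <- creche_cea()
  tn <- tornado(fit)
  expect_true(all(diff(tn$impact) <= 1e-12))
  # the wage touches parents', committee and worker time at once: it
  # dominates the societal-perspective ranking
  expect_equal(tn$input[1], "min_wage")
  # a pure cost category enters the ICER linearly: +/- 1 SD moves it
  # symmetrically about baseline
  adm <- tn[tn$input == "administration", ]
  expect_equal(adm$pct_low, -adm$pct_high, tolerance = 1e-8)
  # zero-SD inputs move nothing
  tz <- tornado(fit, sd_map = c(start_up = 0))
  expect_equal(tz$pct_low, 0)
  expect_equal(tz$pct_high, 0)
})

test_that("proportional sweeps are linear in cost and hyperbolic in effect", {
  fit <- creche_cea()
  sw <- proportional_sweep(fit, "program_cost", multipliers = c(0.5, 1, 2))
  base <- fit$point$icer_life_program
  expect_equal(sw$outcome[sw$multiplier == 1], base)
  expect_equal(sw$outcome[sw$multiplier == 2], 2 * base)
  expect_equal(sw$outcome[sw$multiplier == 0.5], 0.5 * base)
  se <- proportional_sweep(fit, "lives_saved", multipliers = c(0, 0.5, 1, 2))
  expect_true(is.na(se$outcome[se$multiplier == 0]))  # undefined ICER
  expect_equal(se$outcome[se$multiplier == 0.5], 2 * base)
  expect_equal(se$outcome[se$multiplier == 2], base / 2)
  expect_error(proportional_sweep(fit, "not_a_parameter"), "unknown")
})
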