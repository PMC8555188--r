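test_that("expected deaths reproduce the published cohort by band", {
  bands <- default_age_bands()
  sq <- expected_deaths(bands, "status_quo")
  # N x I / 100,000 per band
  expect_equal(sq$per_band$deaths[1], 41.27, tolerance = 0.0002)
  expect_equal(sq$per_band$deaths[2], 37.00, tolerance = 0.0002)
  expect_equal(sq$total, sum(sq$per_band$deaths))
  # cohort CI is the sum of band-level bound deaths; SD recovered from it
  expect_equal(sq$ci_low, 75.63, tolerance = 0.001)
  expect_equal(sq$ci_high, 162.94, tolerance = 0.001)
  expect_equal(sq$sd, 22.27, tolerance = 0.001)
  cr <- expected_deaths(bands, "creche")
  expect_equal(cr$total, 15.60, tolerance = 0.001)
  expect_equal(cr$ci_low, 5.03, tolerance = 0.001)
  expect_equal(cr$ci_high, 61.58, tolerance = 0.001)
})

test_that("zero incidence and invalid inputs behave as specified", {
  bands <- default_age_bands()
  bands$cr_incidence[] <- 0
  bands$cr_ci_low[] <- bands$cr_ci_high[] <- 0
  expect_equal(expected_deaths(bands, "creche")$total, 0)
  bands$sq_incidence[1] <- -1
  expect_error(expected_deaths(bands, "status_quo"), "non-negative")
  bands2 <- default_age_bands()
  bands2$pop_count[2] <- -5
  expect_error(expected_deaths(bands2, "status_quo"), "non-negative")
})

test_that("deaths are additive over bands and scale with the cohort", {
  set.seed(11)
  for (i in 1:5) {
    k <- sample(2:6, 1)
    b <- data.frame(label = paste0("b", 1:k),
                    pop_count = sample(1e3:5e4, k),
                    sq_incidence = runif(k, 0, 200),
                    cr_incidence = runif(k, 0, 80))
    d <- expected_deaths(b, "status_quo")
    expect_equal(d$total, sum(b$pop_count * b$sq_incidence / 1e5))
    b2 <- b
    b2$pop_count <- 2L * b2$pop_count
    d2 <- expected_deaths(b2, "status_quo")
    expect_equal(d2$per_band$deaths, 2 * d$per_band$deaths)
    ls1 <- lives_saved(d, expected_deaths(b, "creche"))
    ls2 <- lives_saved(d2, expected_deaths(b2, "creche"))
    expect_equal(ls2$lives_saved, 2 * ls1$lives_saved)
  }
})

test_that("lives saved differences the scenarios and carries printed CIs", {
  bands <- default_age_bands()
  sq <- expected_deaths(bands, "status_quo")
  cr <- expected_deaths(bands, "creche")
  ls <- lives_saved(sq, cr, ci = c(70.60, 101.36))
  expect_equal(ls$lives_saved, 95.40, tolerance = 0.02 / 95)
  expect_equal(ls$per_band$lives_saved[1], 30.09, tolerance = 0.0002)
  expect_equal(ls$sd, 7.85, tolerance = 0.001)
  # identical scenarios save nothing
  expect_equal(lives_saved(sq, sq)$lives_saved, 0)
  # mismatched band partitions are an error
  b2 <- bands[1:2, ]
  expect_error(lives_saved(sq, expected_deaths(b2, "creche")), "band sets")
})

test_that("sd_from_ci matches the rate-SE formula and its symmetries", {
  expect_equal(sd_from_ci(70.60, 101.36), 7.85, tolerance = 0.001)
  expect_equal(sd_from_ci(28.68, 59.37), 7.83, tolerance = 0.001)
  expect_equal(sd_from_ci(4.2, 4.2), 0)
  expect_error(sd_from_ci(10, 5), "below")
  set.seed(21)
  for (i in 1:10) {
    lo <- runif(1, -50, 50); hi <- lo + runif(1, 0, 100)
    s <- runif(1, -20, 20); k <- runif(1, 0.1, 5)
    expect_equal(sd_from_ci(lo + s, hi + s), sd_from_ci(lo, hi))
    expect_equal(sd_from_ci(k * lo, k * hi), k * sd_from_ci(lo, hi))
  }
})

test_that("risk-ratio application is consistent with the creche incidences", {
  expect_equal(incidence_from_rr(125.45, 0.40), 50.18)
  expect_equal(incidence_from_rr(125.45, 34.00 / 125.45), 34.00)
  expect_equal(incidence_from_rr(77.7, 1.0), 77.7)
  expect_error(incidence_from_rr(100, -0.1), "non-negative")
  # applying the implied band RRs to the status-quo cohort reproduces the
  # creche-scenario deaths
  bands <- default_age_bands()
  rr <- bands$cr_incidence / bands$sq_incidence
  bands$cr_incidence <- incidence_from_rr(bands$sq_incidence, rr)
  cr <- expected_deaths(bands, "creche")
  expect_equal(cr$per_band$deaths,
               expected_deaths(default_age_bands(), "creche")$per_band$deaths,
               tolerance = 0.01 / 15)
})
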