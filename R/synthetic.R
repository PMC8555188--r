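# Synthetic study data: a 54-record, two-area monthly expenditure ledger
# with the published observation-level moments, microsimulated cohort
# outcomes for parameter-recovery checks, and a wage proxy series.

#' Published ledger moments
#'
#' Monthly observation-level moments the generator reproduces: the cost
#' categories of [default_cost_params()] plus program-wide enrollment
#' (mean 40,378, SD 15,572, range 1664-47,992) and functional creches
#' (mean 1554, SD 585, range 91-1600).
#'
#' @return List: `costs` (the [default_cost_params()] table), `enrollment`
#'   and `creches` (named vectors mean/sd/min/max).
#' @export
ledger_moments <- function() {
  list(costs = default_cost_params(),
       enrollment = c(mean = 40378, sd = 15572, min = 1664, max = 47992),
       creches = c(mean = 1554, sd = 585, min = 91, max = 1600))
}

ramp_path <- function(n_months, ramp_months, ramp_start) {
  if (ramp_months <= 1) return(rep(1, n_months))
  pmin(1, ramp_start + (seq_len(n_months) - 1) *
         (1 - ramp_start) / (ramp_months - 1))
}

# Draw one bounded series on a ramp: plateau calibrated so the time-average
# matches the published mean, multiplicative noise, hard-clipped to bounds.
ramp_series <- function(n, m, ramp, noise_cv) {
  plateau <- min(m[["mean"]] / mean(ramp), m[["max"]])
  x <- ramp * plateau * (1 + stats::rnorm(n, 0, noise_cv))
  pmin(pmax(x, m[["min"]]), m[["max"]])
}

#' Generate a synthetic two-area monthly expenditure ledger
#'
#' Emulates the 54 area-month expenditure records of the two study areas
#' (31 calendar months for area 1, the final 23 for area 2). Per-category
#' program-month totals are truncated-normal draws: the published monthly
#' SD and min/max are used directly, and the underlying location is solved
#' so the *truncated* mean equals the published monthly mean (the published
#' mean/SD/range are not jointly attainable by any truncated normal — the
#' real series mixes ramp-up and capacity months — so the mean, which drives
#' every downstream total, is matched exactly and the SD is approximate).
#' Enrollment and creche counts follow a start-up ramp whose plateau is
#' calibrated so their time-averages match the published means, clipped to
#' the published ranges. Monthly program totals are split across the active
#' areas by `area_share`.
#'
#' @param moments A [ledger_moments()] list.
#' @param months Integer vector `c(area1, area2)` of active months; area 2
#'   starts so both end together. Default `c(31, 23)`.
#' @param seed Optional integer seed.
#' @param area_share Cost/enrollment split between areas when both are
#'   active. Default `c(0.5, 0.5)`.
#' @param ramp_months Months for enrollment to reach plateau. Default 9.
#' @param creche_ramp_months Months for the creche count to reach plateau
#'   (creches were established faster than children enrolled). Default 4.
#' @param ramp_start Starting fraction of plateau. Default 0.05.
#' @param noise_cv Multiplicative noise CV on the ramped series. Default
#'   0.04.
#' @return A ledger data.frame (`month`, `area`, `category`, `amount`,
#'   `effort`, `enrollment`, `creches`, `year`) in the format
#'   [build_annual_summary()] consumes.
#' @export
generate_ledger <- function(moments = ledger_moments(), months = c(31, 23),
                            seed = NULL, area_share = c(0.5, 0.5),
                            ramp_months = 9, creche_ramp_months = 4,
                            ramp_start = 0.05, noise_cv = 0.04) {
  stopifnot(length(months) == 2, months[1] >= months[2], months[2] >= 1)
  cp <- moments$costs
  if (any(cp$monthly_max < cp$monthly_mean, na.rm = TRUE) ||
      any(cp$monthly_mean < cp$monthly_min, na.rm = TRUE)) {
    stop("infeasible moments: monthly mean outside [min, max]")
  }
  if (!is.null(seed)) set.seed(seed)
  n_cal <- months[1]
  start2 <- n_cal - months[2] + 1
  # program-wide monthly category totals
  cat_draws <- lapply(seq_len(nrow(cp)), function(i) {
    if (cp$monthly_sd[i] == 0) {
      rep(cp$monthly_mean[i], n_cal)
    } else {
      fi <- fitted_input(cp$category[i], "norm",
                         c(cp$monthly_mean[i], cp$monthly_sd[i]),
                         c(cp$monthly_min[i], cp$monthly_max[i]),
                         target_mean = cp$monthly_mean[i])
      draw_input(fi, n_cal)
    }
  })
  names(cat_draws) <- cp$category
  enr <- ramp_series(n_cal, moments$enrollment,
                     ramp_path(n_cal, ramp_months, ramp_start), noise_cv)
  crc <- ramp_series(n_cal, moments$creches,
                     ramp_path(n_cal, creche_ramp_months, ramp_start),
                     noise_cv)
  share <- area_share / sum(area_share)
  rows <- vector("list", n_cal * 2L)
  k <- 0L
  for (m in seq_len(n_cal)) {
    areas <- if (m >= start2) 1:2 else 1L
    sh <- if (length(areas) == 2) share else 1
    for (j in seq_along(areas)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        month = m, area = areas[j], category = cp$category,
        amount = vapply(cat_draws, `[[`, numeric(1), m) * sh[j],
        effort = 1,
        enrollment = round(enr[m] * sh[j]),
        creches = round(crc[m] * sh[j]),
        year = 2013 + (m + 4) %/% 12,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Simulation configuration for cohort outcomes
#'
#' @param n_per_scenario Children simulated under each scenario. Default
#'   100,000.
#' @param bands Age-band table with scenario incidences (shares taken from
#'   `pop_count`). Default [default_age_bands()].
#' @param attendance An [attendance_distribution()].
#' @param seed Optional integer seed.
#' @return A list of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_per_scenario = 1e5,
                              bands = default_age_bands(),
                              attendance = attendance_distribution(),
                              seed = NULL) {
  check_bands(bands)
  if (any(bands$sq_incidence < 0) || any(bands$cr_incidence < 0)) {
    stop("incidences must be non-negative")
  }
  structure(list(n_per_scenario = n_per_scenario, bands = bands,
                 attendance = attendance, seed = seed),
            class = "sim_cohort_config")
}

#' Microsimulate individual cohort outcomes
#'
#' Draws individual children under both scenarios: age band (multinomial at
#' the band population shares), attendance tier, and a Bernoulli drowning
#' death at the band- and scenario-specific annual cumulative incidence.
#' Supports parameter-recovery checks of the effectiveness stage: at large
#' n the estimated lives saved converges to the deterministic cohort value.
#'
#' @param c A [sim_cohort_config()].
#' @return data.frame: `scenario`, `band`, `attended`, `tier`, `died`.
#' @export
generate_cohort_outcomes <- function(c = sim_cohort_config()) {
  stopifnot(inherits(c, "sim_cohort_config"))
  if (!is.null(c$seed)) set.seed(c$seed)
  bands <- c$bands
  share <- bands$pop_count / sum(bands$pop_count)
  att <- c$attendance
  tiers <- c(names(att$freq_shares), "none")
  out <- lapply(c("status_quo", "creche"), function(sc) {
    inc <- if (sc == "status_quo") bands$sq_incidence else bands$cr_incidence
    n_band <- stats::rmultinom(1, c$n_per_scenario, share)[, 1]
    do.call(rbind, lapply(seq_along(n_band), function(i) {
      n <- n_band[i]
      if (n == 0) return(NULL)
      attended <- stats::runif(n) < att$ever_attended
      tier <- rep("none", n)
      if (any(attended)) {
        tier[attended] <- sample(names(att$freq_shares), sum(attended),
                                 replace = TRUE, prob = att$freq_shares)
      }
      data.frame(scenario = sc, band = bands$label[i],
                 attended = attended,
                 tier = factor(tier, levels = tiers),
                 died = stats::rbinom(n, 1, inc[i] / 1e5),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Estimate lives saved from microsimulated outcomes
#'
#' @param outcomes Output of [generate_cohort_outcomes()].
#' @param per Reporting scale. Default per 100,000 children.
#' @return Estimated deaths averted per `per` children.
#' @export
estimate_lives_saved <- function(outcomes, per = 1e5) {
  r <- tapply(outcomes$died, outcomes$scenario, mean)
  unname(r[["status_quo"]] - r[["creche"]]) * per
}

#' Synthetic wage proxy series
#'
#' Stand-in for the yearly GDP-per-capita observations (2010-2019, 2015
#' USD, expressed as monthly wage equivalents) used to give the minimum
#' wage a distribution in the sensitivity analysis; the real series is not
#' published, so this draws a short normal series with the documented
#' monthly SD.
#'
#' @param n Observations. Default 10.
#' @param mean Monthly wage mean. Default 78.48.
#' @param sd Monthly SD. Default 16.49.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_wage_proxy <- function(n = 10, mean = 78.48, sd = 16.49,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, mean, sd)
}
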