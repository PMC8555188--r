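# Ingredients-based program costing: ledger normalization, fixed-cost
# annualization, annual totals and average costs, monthly trend.

#' Program cost categories and default parameters
#'
#' The nine ingredient categories of the creche program budget, their
#' fixed/variable classification, assumed useful lives (fixed categories:
#' start-up 10 y, equipment 7.5 y, trainings 5 y, creche maintenance 3 y),
#' published annual totals (2015 USD) and the monthly-observation moments
#' (mean, SD, min, max over the 54 area-month records from the two study
#' areas). `monthly_mean` is `annual / 12` so the two columns are exactly
#' consistent; the published rounded monthly figures differ by at most $1.
#'
#' @return A data.frame with columns `category`, `kind` ("fixed" or
#'   "variable"), `useful_life` (years, `NA` for variable), `annual`,
#'   `monthly_mean`, `monthly_sd`, `monthly_min`, `monthly_max`.
#' @examples
#' default_cost_params()
#' @export
default_cost_params <- function() {
  df <- data.frame(
    category = c("start_up", "equipment", "trainings", "creche_maintenance",
                 "wages_field", "community_engagement", "transportation",
                 "field_overhead", "administration"),
    kind = c(rep("fixed", 4), rep("variable", 5)),
    useful_life = c(10, 7.5, 5, 3, NA, NA, NA, NA, NA),
    annual = c(534, 203, 3356, 41803, 540612, 1959, 10662, 7497, 40448),
    monthly_sd  = c(0, 135, 862, 12032, 16329, 149, 490, 313, 1241),
    monthly_min = c(NA, 0, 0, 56, 687, 0, 45, 110, 2348),
    monthly_max = c(NA, 964, 4820, 74719, 50825, 1013, 2940, 1020, 8406),
    stringsAsFactors = FALSE
  )
  df$monthly_mean <- df$annual / 12
  # start-up was a one-off with no observed monthly spread
  df$monthly_min[1] <- df$monthly_max[1] <- df$monthly_mean[1]
  df[, c("category", "kind", "useful_life", "annual", "monthly_mean",
         "monthly_sd", "monthly_min", "monthly_max")]
}

#' Annuity factor
#'
#' Present value of one currency unit per year for `life` years at discount
#' rate `r`: `(1 - (1 + r)^-life) / r`, or `life` when `r = 0`.
#'
#' @param life Useful life in years, positive.
#' @param r Annual discount rate.
#' @return The annuity factor, vectorized over `life`.
#' @export
annuity_factor <- function(life, r = 0.03) {
  if (any(life <= 0)) stop("useful life must be positive")
  if (r == 0) life else (1 - (1 + r)^(-life)) / r
}

#' Annualize a fixed-cost investment
#'
#' Converts a one-time capital outlay into the equivalent annual cost over
#' its useful life at discount rate `r` (equivalent annual cost method):
#' `investment * r / (1 - (1 + r)^-life)`; straight-line `investment / life`
#' when `r = 0`.
#'
#' @param investment One-time outlay (USD).
#' @param life Useful life in years, positive.
#' @param r Annual discount rate, default 0.03.
#' @return Annualized cost (USD/year), vectorized.
#' @examples
#' annualize_fixed(1000, 10, 0.03)  # 117.23
#' @export
annualize_fixed <- function(investment, life, r = 0.03) {
  investment / annuity_factor(life, r)
}

check_ledger <- function(ledger) {
  stopifnot(is.data.frame(ledger))
  need <- c("month", "area", "category", "amount")
  miss <- setdiff(need, names(ledger))
  if (length(miss)) {
    stop("ledger is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(ledger) == 0) stop("ledger is empty")
  if (any(ledger$amount < 0, na.rm = TRUE)) {
    stop("ledger amounts must be non-negative")
  }
  invisible(ledger)
}

lookup_by_year <- function(series, years, what) {
  if (length(series) == 1 && is.null(names(series))) {
    return(rep(series, length(years)))
  }
  idx <- match(as.character(years), names(series))
  if (anyNA(idx)) {
    stop("no ", what, " defined for year ",
         paste(unique(years[is.na(idx)]), collapse = ", "))
  }
  unname(series[idx])
}

#' Normalize an expenditure ledger to creche-attributable 2015 USD
#'
#' Applies an inflation deflator (to 2015 local currency), a currency
#' conversion (to 2015 USD) and the creche-attributable percent-effort share
#' to every record. Records with zero effort (research or non-creche program
#' activity) are zeroed out.
#'
#' @param ledger Ledger data.frame with columns `month`, `area`, `category`,
#'   `amount`, and optionally `effort` (fraction in `[0,1]`, default 1) and
#'   `year` (required when `deflator` or `fx` is a per-year named vector).
#' @param deflator Inflation adjustment to 2015 terms: scalar, or named
#'   vector by year. Default 1.
#' @param fx Currency conversion (USD per unit local currency): scalar, or
#'   named vector by year. Default 1.
#' @param effort Optional scalar or vector of effort shares overriding the
#'   ledger column.
#' @return The ledger with `amount` replaced by the normalized value, and
#'   attribute `normalized = TRUE`.
#' @examples
#' lg <- data.frame(month = 1, area = 1, category = "wages_field",
#'                  amount = 100, year = 2014)
#' normalize_ledger(lg, deflator = c("2014" = 1.06), fx = 0.01282)$amount
#' @export
normalize_ledger <- function(ledger, deflator = 1, fx = 1, effort = NULL) {
  check_ledger(ledger)
  eff <- if (!is.null(effort)) effort
         else if (!is.null(ledger$effort)) ledger$effort
         else 1
  if (any(eff < 0 | eff > 1)) stop("effort shares must lie in [0, 1]")
  needs_year <- (length(deflator) > 1 || !is.null(names(deflator)) ||
                 length(fx) > 1 || !is.null(names(fx)))
  if (needs_year && is.null(ledger$year)) {
    stop("per-year deflator/fx supplied but ledger has no 'year' column")
  }
  d <- if (!is.null(names(deflator))) {
    lookup_by_year(deflator, ledger$year, "deflator")
  } else deflator
  f <- if (!is.null(names(fx))) lookup_by_year(fx, ledger$year, "fx") else fx
  ledger$amount <- ledger$amount * d * f * eff
  ledger$effort <- NULL
  attr(ledger, "normalized") <- TRUE
  ledger
}

# Program-wide calendar-month series: total cost, enrollment and creche
# count summed over areas (enrollment/creches are per area-month, repeated
# across that area-month's category rows).
month_panel <- function(ledger) {
  months <- sort(unique(ledger$month))
  totals <- tapply(ledger$amount, ledger$month, sum)[as.character(months)]
  out <- data.frame(month = months, total = as.numeric(totals))
  for (col in c("enrollment", "creches")) {
    if (!is.null(ledger[[col]])) {
      am <- ledger[!duplicated(ledger[c("month", "area")]), ]
      s <- tapply(am[[col]], am$month, sum)[as.character(months)]
      out[[col]] <- as.numeric(s)
    }
  }
  out
}

#' Annual cost summary from a monthly expenditure ledger
#'
#' Models the steady-state annual cost of the program over a multi-year
#' horizon: every category's annual cost is its mid-to-full-capacity monthly
#' run rate times 12, where capacity months are those whose program-wide
#' enrollment reaches at least `capacity_frac` of the maximum observed.
#' Caseload and functional-creche counts are the capacity-month means.
#' Ledger amounts for fixed categories are treated as already expressed in
#' annualized terms (monthly equivalents); set `fixed_as_investment = TRUE`
#' to instead treat them as raw capital outlays to be summed and converted
#' by [annualize_fixed()] at the categories' useful lives.
#'
#' @param ledger A normalized ledger (see [normalize_ledger()]) with
#'   `enrollment` and `creches` columns.
#' @param cost_params Category table as [default_cost_params()] (supplies
#'   kind and useful life).
#' @param r Discount rate for annualization. Default 0.03.
#' @param horizon Projection horizon in years (steady-state model, recorded
#'   for reporting). Default 10.
#' @param capacity_frac Enrollment fraction of maximum defining a capacity
#'   month. Default 0.5.
#' @param fixed_as_investment Treat fixed-category amounts as raw
#'   investments and annualize their sum. Default `FALSE`.
#' @return An `annual_cost_summary` object; see
#'   [annual_summary_from_totals()] for its fields.
#' @export
build_annual_summary <- function(ledger, cost_params = default_cost_params(),
                                 r = 0.03, horizon = 10,
                                 capacity_frac = 0.5,
                                 fixed_as_investment = FALSE) {
  check_ledger(ledger)
  if (is.null(ledger$enrollment)) stop("ledger has no 'enrollment' column")
  panel <- month_panel(ledger)
  at_cap <- panel$enrollment >= capacity_frac * max(panel$enrollment)
  if (!any(at_cap)) stop("no month reaches the capacity threshold")
  cap_months <- panel$month[at_cap]
  cats <- unique(ledger$category)
  annual <- vapply(cats, function(cc) {
    sub <- ledger[ledger$category == cc, ]
    bym <- tapply(sub$amount, sub$month, sum)
    run <- bym[as.character(cap_months)]
    run[is.na(run)] <- 0
    12 * mean(run)
  }, numeric(1))
  kind <- cost_params$kind[match(cats, cost_params$category)]
  kind[is.na(kind)] <- "variable"
  if (fixed_as_investment) {
    for (cc in cats[kind == "fixed"]) {
      life <- cost_params$useful_life[match(cc, cost_params$category)]
      annual[cc] <- annualize_fixed(sum(ledger$amount[ledger$category == cc]),
                                    life, r)
    }
  }
  caseload <- mean(panel$enrollment[at_cap])
  n_creches <- if (!is.null(panel$creches)) mean(panel$creches[at_cap])
               else NA_real_
  annual_summary_from_totals(annual, caseload = caseload,
                             n_creches = n_creches, kind = kind,
                             r = r, horizon = horizon)
}

#' Annual cost summary from category annual totals
#'
#' Direct construction of the annual cost summary when category-level annual
#' totals are already available (e.g. the published annualized budget).
#'
#' @param annual Named numeric vector of annual category costs (2015 USD).
#' @param caseload Children enrolled per year.
#' @param n_creches Functional creches.
#' @param kind Optional character vector ("fixed"/"variable") parallel to
#'   `annual`; defaults to the classification in [default_cost_params()].
#' @param r,horizon Recorded for reporting.
#' @return An object of class `annual_cost_summary`: `categories` data.frame
#'   (`category`, `kind`, `annual`), `fixed_subtotal`, `variable_subtotal`,
#'   `total`, `caseload`, `n_creches`, `cost_per_child`, `cost_per_creche`,
#'   `r`, `horizon`.
#' @examples
#' p <- default_cost_params()
#' s <- annual_summary_from_totals(setNames(p$annual, p$category),
#'                                 caseload = 40378, n_creches = 1554)
#' s$cost_per_child  # 16.03
#' @export
annual_summary_from_totals <- function(annual, caseload, n_creches,
                                       kind = NULL, r = 0.03, horizon = 10) {
  stopifnot(!is.null(names(annual)), all(annual >= 0))
  if (is.null(kind)) {
    cp <- default_cost_params()
    kind <- cp$kind[match(names(annual), cp$category)]
    kind[is.na(kind)] <- "variable"
  }
  fixed_subtotal <- sum(annual[kind == "fixed"])
  variable_subtotal <- sum(annual[kind == "variable"])
  total <- fixed_subtotal + variable_subtotal
  if (caseload <= 0) stop("caseload must be positive for per-child average")
  structure(
    list(
      categories = data.frame(category = names(annual), kind = kind,
                              annual = as.numeric(annual),
                              stringsAsFactors = FALSE),
      fixed_subtotal = fixed_subtotal,
      variable_subtotal = variable_subtotal,
      total = total,
      caseload = caseload,
      n_creches = n_creches,
      cost_per_child = total / caseload,
      cost_per_creche = if (!is.na(n_creches) && n_creches > 0)
        total / n_creches else NA_real_,
      r = r, horizon = horizon
    ),
    class = "annual_cost_summary"
  )
}

#' @export
print.annual_cost_summary <- function(x, ...) {
  cat("Annual program cost (2015 USD,", x$horizon, "year steady-state)\n")
  print(x$categories, row.names = FALSE)
  cat(sprintf("Fixed subtotal:    %12.0f\n", x$fixed_subtotal))
  cat(sprintf("Variable subtotal: %12.0f\n", x$variable_subtotal))
  cat(sprintf("Total:             %12.0f\n", x$total))
  cat(sprintf("Caseload %0.0f children in %0.0f creches: $%.2f per child, $%.2f per creche\n",
              x$caseload, x$n_creches, x$cost_per_child, x$cost_per_creche))
  invisible(x)
}

#' Monthly cost trend
#'
#' Program-wide monthly totals, per-child costs, and a start-up flag for
#' months whose enrollment is below `capacity_frac` of the maximum (the
#' period when initial investments dominate and the program has not reached
#' operating capacity).
#'
#' @param ledger Ledger with at least two distinct months and an
#'   `enrollment` column.
#' @param capacity_frac Start-up threshold. Default 0.5.
#' @return data.frame: `month`, `total`, `enrollment` (and `creches` when
#'   present), `per_child`, `startup` (logical).
#' @export
monthly_trend <- function(ledger, capacity_frac = 0.5) {
  check_ledger(ledger)
  panel <- month_panel(ledger)
  if (nrow(panel) < 2) stop("monthly trend needs at least two months")
  if (is.null(panel$enrollment)) stop("ledger has no 'enrollment' column")
  panel$per_child <- ifelse(panel$enrollment > 0,
                            panel$total / panel$enrollment, NA_real_)
  panel$startup <- panel$enrollment < capacity_frac * max(panel$enrollment)
  panel
}
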