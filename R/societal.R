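# Societal-perspective costs: opportunity cost of creche workers',
# injury-prevention-committee members' and parents' time, valued off the
# rural minimum wage.

#' Societal cost parameters
#'
#' Inputs for opportunity-cost valuation. A creche runs 4 h/day, 6
#' days/week (part time), staffed by two volunteers (caregiver "Ma" and
#' assistant) each valued at half the minimum monthly wage. Village and
#' union injury prevention committee (VIPC/UIPC) meetings are 3 h with at
#' least 7 members; the per-creche meeting rate defaults to the calibrated
#' 0.5505/month (committees serve many creches). The hourly wage divides the
#' monthly minimum wage by a 192-hour full-time month (48 h/week x 4 weeks).
#'
#' @param min_monthly_wage Minimum monthly wage, 2015 USD. Default 78.48
#'   (8000 BDT).
#' @param hours_per_day,days_per_week,weeks_per_year Creche operating
#'   schedule. Defaults 4, 6, 48.
#' @param fulltime_hours_per_month Hours in a full-time month used to derive
#'   the hourly wage. Default 192.
#' @param workers_per_creche Volunteer workers per creche. Default 2.
#' @param worker_wage_fraction Fraction of the minimum wage valuing one
#'   part-time worker. Default 0.5.
#' @param parent_wage_fraction Fraction of the minimum wage valuing a
#'   parent's fully freed-up time (half the work week). Default 0.5.
#' @param committee_members Members per VIPC/UIPC meeting. Default 7.
#' @param committee_hours_per_meeting Hours per meeting. Default 3.
#' @param committee_meetings_per_month Meetings per month per creche.
#'   Default 0.5505.
#' @param children_per_creche Average children enrolled per creche. Default
#'   40378/1554 (~25.98).
#' @return A list of class `societal_params`.
#' @export
societal_params <- function(min_monthly_wage = 78.48,
                            hours_per_day = 4,
                            days_per_week = 6,
                            weeks_per_year = 48,
                            fulltime_hours_per_month = 192,
                            workers_per_creche = 2,
                            worker_wage_fraction = 0.5,
                            parent_wage_fraction = 0.5,
                            committee_members = 7,
                            committee_hours_per_meeting = 3,
                            committee_meetings_per_month = 0.5505,
                            children_per_creche = 40378 / 1554) {
  p <- list(min_monthly_wage = min_monthly_wage,
            hours_per_day = hours_per_day,
            days_per_week = days_per_week,
            weeks_per_year = weeks_per_year,
            fulltime_hours_per_month = fulltime_hours_per_month,
            workers_per_creche = workers_per_creche,
            worker_wage_fraction = worker_wage_fraction,
            parent_wage_fraction = parent_wage_fraction,
            committee_members = committee_members,
            committee_hours_per_meeting = committee_hours_per_meeting,
            committee_meetings_per_month = committee_meetings_per_month,
            children_per_creche = children_per_creche)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && v >= 0, logical(1))]
  if (length(bad)) stop("negative or non-numeric parameter(s): ",
                        paste(bad, collapse = ", "))
  if (children_per_creche <= 0) stop("children_per_creche must be positive")
  structure(p, class = "societal_params")
}

#' Creche attendance distribution
#'
#' Utilization of the creches: the fraction of exposed children who ever
#' attended, and among attenders the split across weekly-frequency tiers
#' (>= 5 days, 2-4 days, < 2 days). Each tier's `freq_weights` entry is the
#' fraction of a full 6-day week that tier represents (defaults 1, 1/2,
#' 1/6); the overall utilization factor is
#' `ever_attended * sum(shares * weights)`.
#'
#' @param ever_attended Fraction of exposed children who ever attended.
#'   Default 0.58.
#' @param freq_shares Tier shares among attenders, summing to 1. Default
#'   `c(0.63, 0.27, 0.10)`.
#' @param freq_weights Fraction of a full week per tier, each in `[0,1]`.
#' @return A list of class `attendance_distribution` with the inputs and the
#'   derived `utilization`.
#' @examples
#' attendance_distribution()$utilization  # ~0.4534
#' @export
attendance_distribution <- function(ever_attended = 0.58,
                                    freq_shares = c(ge5 = 0.63,
                                                    d2to4 = 0.27,
                                                    lt2 = 0.10),
                                    freq_weights = c(1, 1 / 2, 1 / 6)) {
  if (ever_attended < 0 || ever_attended > 1) {
    stop("ever_attended must be in [0, 1]")
  }
  if (abs(sum(freq_shares) - 1) > 1e-8) stop("freq_shares must sum to 1")
  if (any(freq_weights < 0 | freq_weights > 1)) {
    stop("freq_weights must lie in [0, 1]")
  }
  structure(list(ever_attended = ever_attended,
                 freq_shares = freq_shares,
                 freq_weights = freq_weights,
                 utilization = ever_attended * sum(freq_shares * freq_weights)),
            class = "attendance_distribution")
}

#' Opportunity cost of creche workers' time
#'
#' Two part-time volunteers per creche, each valued at
#' `worker_wage_fraction` of the minimum monthly wage for 12 months. Annual
#' volunteer hours are `workers x hours/day x days/week x weeks/year`.
#'
#' @param p A [societal_params()] object.
#' @return List: `hours_per_creche`, `per_creche` (USD/creche/year),
#'   `per_child` (USD/child/year).
#' @examples
#' worker_time_cost(societal_params())  # $941.76/creche, $36.25/child
#' @export
worker_time_cost <- function(p = societal_params()) {
  stopifnot(inherits(p, "societal_params"))
  per_creche <- p$workers_per_creche * p$worker_wage_fraction *
    p$min_monthly_wage * 12
  hours <- p$workers_per_creche * p$hours_per_day * p$days_per_week *
    p$weeks_per_year
  list(hours_per_creche = hours,
       per_creche = per_creche,
       per_child = per_creche / p$children_per_creche)
}

#' Opportunity cost of VIPC/UIPC members' time
#'
#' Person-hours per creche-year are `members x hours/meeting x
#' meetings/month x 12`, valued at the hourly equivalent of the minimum wage
#' (`wage / fulltime_hours_per_month`).
#'
#' @param p A [societal_params()] object.
#' @return List: `hours_per_creche`, `per_creche`, `per_child`.
#' @examples
#' committee_time_cost(societal_params())  # 138.7 h, $56.70/creche, $2.18/child
#' @export
committee_time_cost <- function(p = societal_params()) {
  stopifnot(inherits(p, "societal_params"))
  hours <- p$committee_members * p$committee_hours_per_meeting *
    p$committee_meetings_per_month * 12
  per_creche <- hours * p$min_monthly_wage / p$fulltime_hours_per_month
  list(hours_per_creche = hours,
       per_creche = per_creche,
       per_child = per_creche / p$children_per_creche)
}

#' Economic value of parents' freed-up time
#'
#' One parent per enrolled child is freed for the creche's operating hours
#' (half the work week), valued at `parent_wage_fraction` of the minimum
#' wage and scaled by the utilization factor of [attendance_distribution()].
#' Returned negative: it is a saving, not a cost.
#'
#' @param p A [societal_params()] object.
#' @param a An [attendance_distribution()] object.
#' @return List: `utilization`, `hours_per_child` (freed hours actually
#'   used), `per_child` (negative USD/child/year), `per_creche`.
#' @examples
#' parent_time_value(societal_params(), attendance_distribution())  # -$213.48
#' @export
parent_time_value <- function(p = societal_params(),
                              a = attendance_distribution()) {
  stopifnot(inherits(p, "societal_params"),
            inherits(a, "attendance_distribution"))
  u <- a$utilization
  per_child <- -u * p$parent_wage_fraction * p$min_monthly_wage * 12
  hours <- u * p$hours_per_day * p$days_per_week * p$weeks_per_year
  list(utilization = u,
       hours_per_child = hours,
       per_child = per_child,
       per_creche = per_child * p$children_per_creche)
}

#' Societal cost per child enrolled
#'
#' Assembles the societal perspective: worker time + committee time +
#' program cost, with and without the (negative) value of parents' freed-up
#' time.
#'
#' @param worker,committee,parent,program Per-child annual USD components
#'   (parent is negative = saving). Each may also be the list returned by
#'   the corresponding component function, in which case `$per_child` is
#'   taken.
#' @return An object of class `societal_cost`: the four components plus
#'   `total_with_parents` and `total_without_parents` (USD/child/year).
#' @examples
#' societal_per_child(36.25, 2.18, -213.48, 16.03)
#' @export
societal_per_child <- function(worker, committee, parent, program) {
  take <- function(x) if (is.list(x)) x$per_child else as.numeric(x)
  w <- take(worker); cm <- take(committee); pa <- take(parent)
  pr <- take(program)
  structure(list(worker_time = w, committee_time = cm, parent_time = pa,
                 program_cost = pr,
                 total_with_parents = w + cm + pa + pr,
                 total_without_parents = w + cm + pr),
            class = "societal_cost")
}

#' @export
print.societal_cost <- function(x, ...) {
  cat("Societal cost per child enrolled (2015 USD/year; negative = saving)\n")
  cat(sprintf("  Creche workers' time:   %9.2f\n", x$worker_time))
  cat(sprintf("  VIPC/UIPC members' time:%9.2f\n", x$committee_time))
  cat(sprintf("  Parents' freed-up time: %9.2f\n", x$parent_time))
  cat(sprintf("  Program cost:           %9.2f\n", x$program_cost))
  cat(sprintf("  Total (parents valued):     %9.2f\n", x$total_with_parents))
  cat(sprintf("  Total (parents not valued): %9.2f\n",
              x$total_without_parents))
  invisible(x)
}
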