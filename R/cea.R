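# Incremental cost-effectiveness ratios, WTP classification, break-even
# analysis, and the vectorized evaluation engine shared by the point
# estimate, PSA, tornado and sweep code paths.

#' Willingness-to-pay threshold
#'
#' GDP-per-capita based benchmark for classifying an ICER per DALY averted:
#' at most 1x GDP is "very cost-effective", at most 3x GDP "cost-effective".
#'
#' @param gdp_per_capita GDP per capita, 2015 USD/year. Default 1248.48
#'   (Bangladesh, 2015).
#' @param multipliers Named multipliers `c(very = 1, acceptable = 3)`.
#' @return A list of class `wtp_threshold`.
#' @export
wtp_threshold <- function(gdp_per_capita = 1248.48,
                          multipliers = c(very = 1, acceptable = 3)) {
  if (gdp_per_capita <= 0 || any(multipliers <= 0)) {
    stop("threshold values must be positive")
  }
  structure(list(gdp_per_capita = gdp_per_capita, multipliers = multipliers),
            class = "wtp_threshold")
}

#' Incremental cost for the cohort
#'
#' Scales an unrounded per-child annual cost to the modelled cohort.
#'
#' @param per_child_cost USD per child per year (may be negative for net
#'   savings).
#' @param cohort_n Cohort size. Default 100,000.
#' @return `per_child_cost * cohort_n`.
#' @export
incremental_cost <- function(per_child_cost, cohort_n = 1e5) {
  if (cohort_n <= 0) stop("cohort_n must be positive")
  per_child_cost * cohort_n
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (USD/year for the cohort).
#' @param effect Incremental effect (lives saved or DALYs averted); must be
#'   non-zero.
#' @return `delta_cost / effect`. Negative values indicate a dominant
#'   (cost-saving) intervention; see [classify_wtp()].
#' @export
icer <- function(delta_cost, effect) {
  if (any(effect == 0)) stop("ICER undefined: incremental effect is zero")
  delta_cost / effect
}

#' Classify an ICER per DALY against a WTP threshold
#'
#' @param icer_per_daly USD per DALY averted (vectorized).
#' @param t A [wtp_threshold()] object.
#' @return Character vector: `"dominant (cost-saving)"` for negative ICERs,
#'   `"very cost-effective"` up to 1x GDP, `"cost-effective"` up to 3x GDP,
#'   else `"not cost-effective"`.
#' @examples
#' classify_wtp(c(575, 1953, -5703, 5000))
#' @export
classify_wtp <- function(icer_per_daly, t = wtp_threshold()) {
  stopifnot(inherits(t, "wtp_threshold"))
  g <- t$gdp_per_capita * t$multipliers
  ifelse(icer_per_daly < 0, "dominant (cost-saving)",
    ifelse(icer_per_daly <= g[["very"]], "very cost-effective",
      ifelse(icer_per_daly <= g[["acceptable"]], "cost-effective",
             "not cost-effective")))
}

# Baseline parameter list consumed by cea_engine(). `costs` is an
# annual_cost_summary, `soc` a societal_params, `att` an
# attendance_distribution.
cea_baseline <- function(lives, yll, costs, soc, att, cohort_n = 1e5) {
  cats <- stats::setNames(costs$categories$annual, costs$categories$category)
  n_creches <- costs$n_creches
  cpc <- costs$caseload / n_creches
  c(as.list(cats),
    list(lives_saved = lives, yll = yll,
         n_creches = n_creches, children_per_creche = cpc,
         min_wage = soc$min_monthly_wage,
         committee_meetings = soc$committee_meetings_per_month,
         utilization = att$utilization,
         workers_per_creche = soc$workers_per_creche,
         worker_wage_fraction = soc$worker_wage_fraction,
         parent_wage_fraction = soc$parent_wage_fraction,
         committee_members = soc$committee_members,
         committee_hours_per_meeting = soc$committee_hours_per_meeting,
         fulltime_hours_per_month = soc$fulltime_hours_per_month,
         cohort_n = cohort_n,
         cost_categories = names(cats)))
}

# Vectorized model evaluation. `overrides` is a named list of equal-length
# vectors replacing baseline entries (cost categories are on the annual
# scale). Returns a data.frame with per-child costs, incremental costs and
# the six ICERs. Draws where lives_saved == 0 yield NA ICERs.
cea_engine <- function(base, overrides = list()) {
  n <- if (length(overrides)) max(lengths(overrides)) else 1L
  get <- function(name) {
    v <- if (name %in% names(overrides)) overrides[[name]] else base[[name]]
    rep_len(v, n)
  }
  cat_total <- Reduce(`+`, lapply(base$cost_categories, get))
  cpc <- get("children_per_creche")
  caseload <- get("n_creches") * cpc
  wage <- get("min_wage")
  lives <- get("lives_saved")
  yll <- get("yll")
  pc_program <- cat_total / caseload
  worker_pc <- get("workers_per_creche") * get("worker_wage_fraction") *
    wage * 12 / cpc
  committee_pc <- get("committee_members") *
    get("committee_hours_per_meeting") * get("committee_meetings") * 12 *
    wage / get("fulltime_hours_per_month") / cpc
  parent_pc <- -get("utilization") * get("parent_wage_fraction") * wage * 12
  pc_swp <- pc_program + worker_pc + committee_pc + parent_pc
  pc_swop <- pc_program + worker_pc + committee_pc
  cn <- get("cohort_n")
  dalys <- lives * yll
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  data.frame(
    total_annual_cost = cat_total,
    caseload = caseload,
    per_child_program = pc_program,
    worker_per_child = worker_pc,
    committee_per_child = committee_pc,
    parent_per_child = parent_pc,
    per_child_societal_with_parents = pc_swp,
    per_child_societal_without_parents = pc_swop,
    lives_saved = lives,
    dalys_averted = dalys,
    inc_cost_program = pc_program * cn,
    inc_cost_societal_with_parents = pc_swp * cn,
    inc_cost_societal_without_parents = pc_swop * cn,
    icer_life_program = safe_div(pc_program * cn, lives),
    icer_daly_program = safe_div(pc_program * cn, dalys),
    icer_life_societal_with_parents = safe_div(pc_swp * cn, lives),
    icer_daly_societal_with_parents = safe_div(pc_swp * cn, dalys),
    icer_life_societal_without_parents = safe_div(pc_swop * cn, lives),
    icer_daly_societal_without_parents = safe_div(pc_swop * cn, dalys)
  )
}

#' Break-even analysis against a WTP threshold
#'
#' Solves for the value of one axis at which the per-DALY ICER equals
#' `multiplier` times GDP per capita, holding everything else at the model
#' state: either the per-child cost (`axis = "cost"`, holding the effect) or
#' the number of lives saved (`axis = "effect"`, holding the cost).
#'
#' @param state A fitted [creche_cea()] object, or a list with
#'   `delta_cost` (cohort incremental cost), `lives_saved`, `dalys_averted`
#'   and optionally `cohort_n` (default 100,000). When a fitted object is
#'   given, `perspective` selects which incremental cost is used.
#' @param axis `"cost"` or `"effect"`.
#' @param multiplier WTP multiplier of GDP per capita. Default 3.
#' @param t A [wtp_threshold()] object.
#' @param perspective For fitted objects: `"program"`,
#'   `"societal_with_parents"` or `"societal_without_parents"`.
#' @return The break-even per-child cost (USD/child/year) or lives saved
#'   (per cohort/year).
#' @examples
#' breakeven(list(delta_cost = 1602556, lives_saved = 95.41,
#'                dalys_averted = 2788.59), axis = "effect", multiplier = 1)
#' @export
breakeven <- function(state, axis = c("cost", "effect"), multiplier = 3,
                      t = wtp_threshold(), perspective = "program") {
  axis <- match.arg(axis)
  if (inherits(state, "creche_cea")) {
    state <- list(
      delta_cost = state$point[[paste0("inc_cost_", perspective)]],
      lives_saved = state$point$lives_saved,
      dalys_averted = state$point$dalys_averted,
      cohort_n = state$cohort_n
    )
  }
  cn <- if (is.null(state$cohort_n)) 1e5 else state$cohort_n
  wtp <- multiplier * t$gdp_per_capita
  if (state$lives_saved <= 0) stop("break-even undefined for zero effect")
  if (axis == "cost") {
    wtp * state$dalys_averted / cn
  } else {
    if (state$delta_cost < 0) {
      stop("no break-even on the effect axis: the intervention is ",
           "cost-saving at any positive effect")
    }
    yll <- state$dalys_averted / state$lives_saved
    state$delta_cost / (wtp * yll)
  }
}
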