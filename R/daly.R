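# DALY conversion. In rural Bangladesh a submersed child either dies within
# 24 h or survives without disability, so years lived with disability are
# zero and DALYs equal discounted years of life lost.

#' DALY (YLL) parameters
#'
#' @param discount_rate Annual discount rate for future life years, as a
#'   fraction in `[0, 1)`. Default 0.03.
#' @param life_expectancy Life expectancy at birth, years. Default 72.2.
#' @param mean_age_at_death Mean age at drowning death, years. Default 2.3.
#' @return A list of class `daly_params`.
#' @export
daly_params <- function(discount_rate = 0.03, life_expectancy = 72.2,
                        mean_age_at_death = 2.3) {
  if (discount_rate < 0 || discount_rate >= 1) {
    stop("discount_rate must be in [0, 1)")
  }
  if (mean_age_at_death < 0) stop("mean_age_at_death must be non-negative")
  if (life_expectancy <= mean_age_at_death) {
    stop("life_expectancy must exceed mean_age_at_death")
  }
  structure(list(discount_rate = discount_rate,
                 life_expectancy = life_expectancy,
                 mean_age_at_death = mean_age_at_death),
            class = "daly_params")
}

#' Discounted years of life lost per death
#'
#' Continuous-time discounting of the remaining life span `L - a`:
#' `(1 - exp(-r (L - a))) / r`, the WHO DALY-template form without age
#' weighting; the undiscounted limit `L - a` is used when `r = 0`. At the
#' defaults (r = 0.03, L = 72.2, a = 2.3) this gives 29.24 discounted years
#' per under-five drowning death. (The annual-compounding annuity form gives
#' 29.12 and is not used.)
#'
#' @param p A [daly_params()] object.
#' @return Discounted YLL per death (scalar).
#' @examples
#' yll_per_death(daly_params())          # ~29.24
#' yll_per_death(daly_params(0))         # 69.9, undiscounted
#' @export
yll_per_death <- function(p = daly_params()) {
  stopifnot(inherits(p, "daly_params"))
  span <- p$life_expectancy - p$mean_age_at_death
  r <- p$discount_rate
  if (r == 0) span else (1 - exp(-r * span)) / r
}

#' DALYs averted by the intervention
#'
#' Lives saved times discounted YLL per death. Years lived with disability
#' are zero by assumption, so this is the full DALY change.
#'
#' @param effect Either an `effect_estimate` (from [lives_saved()]) or a
#'   numeric number of lives saved.
#' @param p A [daly_params()] object.
#' @return DALYs averted (same cohort scale as `effect`).
#' @examples
#' dalys_averted(95.41)  # ~2789
#' @export
dalys_averted <- function(effect, p = daly_params()) {
  lives <- if (inherits(effect, "effect_estimate")) effect$lives_saved
           else as.numeric(effect)
  if (any(lives < 0)) stop("lives saved must be non-negative")
  lives * yll_per_death(p)
}
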