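# Probabilistic sensitivity analysis: fitted truncated input distributions,
# Monte Carlo over the CEA model, univariate tornado, proportional sweeps.

fam_pfun <- function(family) {
  switch(family,
         norm = function(q, p) stats::pnorm(q, p[1], p[2]),
         lnorm = function(q, p) stats::plnorm(q, p[1], p[2]),
         gamma = function(q, p) stats::pgamma(q, shape = p[1], rate = p[2]),
         pois = function(q, p) stats::ppois(q, p[1]),
         unif = function(q, p) stats::punif(q, p[1], p[2]),
         stop("unknown family: ", family))
}

fam_qfun <- function(family) {
  switch(family,
         norm = function(u, p) stats::qnorm(u, p[1], p[2]),
         lnorm = function(u, p) stats::qlnorm(u, p[1], p[2]),
         gamma = function(u, p) stats::qgamma(u, shape = p[1], rate = p[2]),
         pois = function(u, p) stats::qpois(u, p[1]),
         unif = function(u, p) stats::qunif(u, p[1], p[2]),
         stop("unknown family: ", family))
}

fam_dfun <- function(family) {
  switch(family,
         norm = function(x, p) stats::dnorm(x, p[1], p[2]),
         lnorm = function(x, p) stats::dlnorm(x, p[1], p[2]),
         gamma = function(x, p) stats::dgamma(x, shape = p[1], rate = p[2]),
         unif = function(x, p) stats::dunif(x, p[1], p[2]),
         stop("unknown family: ", family))
}

fam_mean <- function(family, p) {
  switch(family,
         norm = p[1],
         lnorm = exp(p[1] + p[2]^2 / 2),
         gamma = p[1] / p[2],
         pois = p[1],
         unif = (p[1] + p[2]) / 2,
         point = p[1],
         stop("unknown family: ", family))
}

# Mean of the distribution truncated to [a, b].
trunc_mean <- function(family, p, a, b) {
  pf <- fam_pfun(family)
  if (family == "norm") {
    # closed form; when the window carries essentially no mass the
    # truncated mean collapses onto the nearer bound
    al <- (a - p[1]) / p[2]; be <- (b - p[1]) / p[2]
    z <- stats::pnorm(be) - stats::pnorm(al)
    if (z < 1e-12) return(if (al > 0) a else b)
    return(p[1] + p[2] * (stats::dnorm(al) - stats::dnorm(be)) / z)
  }
  if (family == "pois") {
    lo <- max(0, ceiling(a)); hi <- min(floor(b), stats::qpois(1 - 1e-12, p[1]))
    if (hi < lo) return(NA_real_)
    k <- lo:hi
    w <- stats::dpois(k, p[1])
    return(sum(k * w) / sum(w))
  }
  mass <- pf(b, p) - pf(a, p)
  if (!is.finite(mass) || mass <= 0) return(NA_real_)
  df <- fam_dfun(family)
  num <- stats::integrate(function(x) x * df(x, p), a, b,
                          rel.tol = 1e-9, subdivisions = 500L)$value
  num / mass
}

# Shift (location families) or scale (positive families) the parameters so
# the truncated distribution's mean equals `target`.
recenter_params <- function(family, p, a, b, target) {
  if (family == "point") return(c(value = target))
  shift_fam <- family %in% c("norm", "unif")
  adj <- if (shift_fam) {
    function(c) {
      q <- p
      if (family == "norm") q[1] <- p[1] + c else q[1:2] <- p[1:2] + c
      q
    }
  } else {
    function(c) {  # c = log scale factor
      k <- exp(c)
      q <- p
      if (family == "lnorm") q[1] <- p[1] + c
      else if (family == "gamma") q[2] <- p[2] / k
      else if (family == "pois") q[1] <- p[1] * k
      q
    }
  }
  g <- function(c) trunc_mean(family, adj(c), a, b) - target
  g0 <- g(0)
  if (is.finite(g0) && abs(g0) < 1e-10 * max(1, abs(target))) return(p)
  width <- if (shift_fam) {
    w <- if (family == "norm") p[2] else (p[2] - p[1])
    max(w, abs(target - fam_mean(family, p)), 1e-8)
  } else 1
  # scan outward for a finite sign change (g is increasing where defined;
  # far-out shifts/scales can leave the window empty, yielding NA)
  cand <- sort(unique(c(-width * 2^(0:10), 0, width * 2^(0:10))))
  gv <- vapply(cand, function(ci) {
    v <- suppressWarnings(try(g(ci), silent = TRUE))
    if (inherits(v, "try-error") || !is.finite(v)) NA_real_ else v
  }, numeric(1))
  keep <- which(!is.na(gv))
  bracket <- NULL
  for (j in seq_along(keep)[-1]) {
    i1 <- keep[j - 1L]; i2 <- keep[j]
    if (gv[i1] * gv[i2] <= 0) { bracket <- c(cand[i1], cand[i2]); break }
  }
  if (is.null(bracket)) {
    stop("cannot recenter ", family, " distribution to mean ", target,
         " within truncation bounds [", a, ", ", b, "]")
  }
  c_star <- stats::uniroot(g, bracket, tol = 1e-10)$root
  adj(c_star)
}

#' Construct a fitted, truncated, recentered model input
#'
#' A probability distribution for one PSA input: a parametric family,
#' truncation at the observed minimum and maximum, and recentering so the
#' truncated distribution's mean equals the mean used by the deterministic
#' costing model (so the simulation and the costing model agree on central
#' values). Draws use inverse-CDF sampling restricted to the truncation
#' window, so they are exact and reproducible under a seed.
#'
#' @param name Input name (must match a model parameter or cost category).
#' @param family One of `"norm"`, `"lnorm"`, `"gamma"`, `"pois"`, `"unif"`,
#'   or `"point"` (degenerate).
#' @param params Numeric parameter vector for the family (`point`: the
#'   value).
#' @param truncation Length-2 numeric `(min, max)`; may be infinite.
#' @param target_mean Mean to recenter to; default the family mean.
#' @return An object of class `fitted_input`.
#' @export
fitted_input <- function(name, family, params,
                         truncation = c(-Inf, Inf),
                         target_mean = NULL) {
  stopifnot(length(truncation) == 2, truncation[1] <= truncation[2])
  if (is.null(target_mean)) target_mean <- fam_mean(family, params)
  if (family != "point" &&
      (target_mean < truncation[1] || target_mean > truncation[2])) {
    stop("target mean ", target_mean, " lies outside truncation bounds")
  }
  structure(list(name = name, family = family,
                 params = as.numeric(params),
                 truncation = as.numeric(truncation),
                 target_mean = target_mean),
            class = "fitted_input")
}

#' @export
print.fitted_input <- function(x, ...) {
  cat(sprintf("fitted_input '%s': %s(%s), truncated [%g, %g], mean %.4g\n",
              x$name, x$family,
              paste(signif(x$params, 5), collapse = ", "),
              x$truncation[1], x$truncation[2], x$target_mean))
  invisible(x)
}

#' Draw from a fitted input
#'
#' Recenters the distribution to `target_mean` (a location shift for
#' normal/uniform, a scale change for lognormal/gamma/Poisson, solved so the
#' *truncated* mean matches), then samples within the truncation window by
#' inverse-CDF.
#'
#' @param fi A [fitted_input()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_input <- function(fi, n) {
  stopifnot(inherits(fi, "fitted_input"))
  if (fi$family == "point") return(rep(fi$target_mean, n))
  a <- fi$truncation[1]; b <- fi$truncation[2]
  p <- recenter_params(fi$family, fi$params, a, b, fi$target_mean)
  pf <- fam_pfun(fi$family); qf <- fam_qfun(fi$family)
  if (fi$family == "pois") {
    ua <- pf(ceiling(a) - 1, p); ub <- pf(floor(b), p)
  } else {
    ua <- pf(a, p); ub <- pf(b, p)
  }
  if (ub <= ua) stop("truncation window has no probability mass")
  x <- qf(ua + (ub - ua) * stats::runif(n), p)
  pmin(pmax(x, a), b)
}

#' Fit a probability distribution to observed input data
#'
#' Maximum-likelihood fits of each candidate family to a series of monthly
#' observations, selected by AIC; truncation bounds are the observed minimum
#' and maximum, and the distribution is recentered to `target_mean` (by
#' default the sample mean, in the pipeline the costing-model mean). A
#' zero-variance series yields a degenerate point mass.
#'
#' @param x Numeric observations, at least 5.
#' @param families Candidate families among `"norm"`, `"lnorm"`, `"gamma"`,
#'   `"pois"`, `"unif"`. Lognormal/gamma are skipped for non-positive data,
#'   Poisson for non-integer data. The uniform is not a default candidate:
#'   its range-MLE likelihood depends on the support and systematically
#'   dominates AIC comparisons on any bounded sample, so it is only
#'   considered when requested explicitly.
#' @param target_mean Recentering mean. Default `mean(x)`.
#' @param name Input name carried into the result.
#' @return A [fitted_input()] with an extra `aic` element (data.frame of the
#'   per-family AICs).
#' @export
fit_input <- function(x, families = c("norm", "lnorm", "gamma", "pois"),
                      target_mean = mean(x), name = "input") {
  x <- as.numeric(x)
  if (length(x) < 5) stop("need at least 5 observations to fit an input")
  if (stats::sd(x) == 0) {
    return(fitted_input(name, "point", x[1], c(x[1], x[1]), target_mean))
  }
  families <- match.arg(families,
                        c("norm", "lnorm", "gamma", "pois", "unif"),
                        several.ok = TRUE)
  if (any(x <= 0)) families <- setdiff(families, c("lnorm", "gamma"))
  if (any(x != round(x)) || any(x < 0)) families <- setdiff(families, "pois")
  fits <- list()
  aics <- numeric(0)
  for (fam in setdiff(families, "unif")) {
    f <- try(suppressWarnings(
      fitdistrplus::fitdist(x, fam,
                            discrete = fam == "pois")), silent = TRUE)
    if (!inherits(f, "try-error") && is.finite(f$aic)) {
      fits[[fam]] <- as.numeric(f$estimate)
      aics[fam] <- f$aic
    }
  }
  if ("unif" %in% families) {
    # MLE for a uniform is the sample range; AIC computed in closed form
    rng <- range(x)
    fits[["unif"]] <- rng
    aics["unif"] <- 2 * 2 + 2 * length(x) * log(diff(rng))
  }
  if (!length(fits)) stop("no candidate family could be fitted")
  best <- names(which.min(aics))
  fi <- fitted_input(name, best, fits[[best]], range(x), target_mean)
  fi$aic <- data.frame(family = names(aics), aic = as.numeric(aics),
                       row.names = NULL)
  fi
}

#' Lognormal effect-size distribution from a mean and 95% CI
#'
#' The effect (lives saved) enters the PSA as a lognormal whose *arithmetic*
#' mean is the point estimate and whose SD is recovered from the CI by
#' [sd_from_ci()]; the log-scale parameters follow from moment matching:
#' `sigma^2 = log(1 + (sd/mean)^2)`, `mu = log(mean) - sigma^2/2`. The
#' lognormal support guarantees every draw is positive.
#'
#' @param mean_lives Point estimate of lives saved.
#' @param ci Length-2 95% CI.
#' @return A [fitted_input()] named `"lives_saved"`.
#' @examples
#' effect_distribution(95.41, c(70.60, 101.36))
#' @export
effect_distribution <- function(mean_lives, ci) {
  s <- sd_from_ci(ci[1], ci[2])
  if (s == 0) {
    return(fitted_input("lives_saved", "point", mean_lives,
                        c(mean_lives, mean_lives), mean_lives))
  }
  sigma2 <- log(1 + (s / mean_lives)^2)
  mu <- log(mean_lives) - sigma2 / 2
  fitted_input("lives_saved", "lnorm", c(mu, sqrt(sigma2)), c(0, Inf),
               target_mean = mean_lives)
}

#' Default PSA input set
#'
#' The inputs varied in the simulation, mirroring the published analysis:
#' each program cost category (annual scale, normal, truncated at 12x the
#' observed monthly min/max), the effect size (lognormal via
#' [effect_distribution()]), the minimum wage (normal, SD from the
#' GDP-per-capita proxy series), the committee meeting rate, and children
#' per creche. Meeting hours and members per meeting stay fixed. When a
#' monthly expenditure `ledger` is supplied, the cost-category families are
#' instead chosen by [fit_input()] on its observations.
#'
#' @param object A fitted [creche_cea()] object.
#' @param ledger Optional normalized ledger whose per-category monthly
#'   observations are fitted with [fit_input()].
#' @return Named list of [fitted_input()] objects.
#' @export
default_psa_inputs <- function(object, ledger = NULL) {
  stopifnot(inherits(object, "creche_cea"))
  cfg <- object$config
  cp <- cfg$costs$params
  base <- object$baseline
  inputs <- list()
  if (is.null(ledger)) {
    for (i in seq_len(nrow(cp))) {
      cat <- cp$category[i]
      ann <- base[[cat]]
      sd_a <- cp$monthly_sd[i] * 12
      inputs[[cat]] <- if (sd_a == 0) {
        fitted_input(cat, "point", ann, c(ann, ann), ann)
      } else {
        fitted_input(cat, "norm", c(ann, sd_a),
                     c(cp$monthly_min[i], cp$monthly_max[i]) * 12,
                     target_mean = ann)
      }
    }
  } else {
    for (cat in unique(ledger$category)) {
      obs <- 12 * ledger$amount[ledger$category == cat]
      tm <- if (cat %in% names(base)) base[[cat]] else mean(obs)
      inputs[[cat]] <- if (stats::sd(obs) == 0) {
        fitted_input(cat, "point", tm, range(obs), tm)
      } else fit_input(obs, target_mean = tm, name = cat)
    }
  }
  eff <- object$effect
  inputs$lives_saved <- effect_distribution(eff$lives_saved,
                                            c(eff$ci_low, eff$ci_high))
  psa <- cfg$psa
  w <- base$min_wage
  wb <- if (is.null(psa$wage_bounds)) w + c(-2, 2) * psa$wage_sd
        else psa$wage_bounds
  inputs$min_wage <- fitted_input("min_wage", "norm", c(w, psa$wage_sd), wb,
                                  target_mean = w)
  m <- base$committee_meetings
  inputs$committee_meetings <- fitted_input(
    "committee_meetings", "norm", c(m, psa$meetings_cv * m), c(0, 2 * m),
    target_mean = m)
  cpc <- base$children_per_creche
  inputs$children_per_creche <- fitted_input(
    "children_per_creche", "norm", c(cpc, psa$children_sd),
    psa$children_bounds, target_mean = cpc)
  inputs
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of the input distributions through the CEA
#' model: each iteration draws one value from every input, re-evaluates the
#' model, and records all six ICERs; 95% uncertainty intervals are the
#' 2.5th/97.5th percentiles of the draws. Runs are reproducible: the same
#' seed and configuration give identical output.
#'
#' @param object A fitted [creche_cea()] object.
#' @param n Iterations. Default the config's `psa$iterations` (100,000).
#' @param seed Optional integer seed.
#' @param inputs Named list of [fitted_input()]s; default
#'   [default_psa_inputs()].
#' @return An object of class `psa_result`: `draws` (data.frame of
#'   per-iteration model outcomes), `ci` (2.5/50/97.5 percentiles per
#'   outcome), `means`, `n`, `seed`.
#' @export
run_psa <- function(object, n = NULL, seed = NULL, inputs = NULL) {
  stopifnot(inherits(object, "creche_cea"))
  if (is.null(n)) n <- object$config$psa$iterations
  if (n < 1) stop("need at least one iteration")
  if (is.null(inputs)) inputs <- default_psa_inputs(object)
  if (!is.null(seed)) set.seed(seed)
  names(inputs) <- vapply(inputs, `[[`, character(1), "name")
  inputs <- inputs[order(names(inputs))]  # draw order independent of caller
  overrides <- lapply(inputs, draw_input, n = n)
  draws <- cea_engine(object$baseline, overrides)
  icer_cols <- grep("^icer_", names(draws), value = TRUE)
  ci <- t(vapply(draws[icer_cols], stats::quantile,
                 numeric(3), probs = c(0.025, 0.5, 0.975), na.rm = TRUE))
  ci <- data.frame(outcome = rownames(ci), lo = ci[, 1], median = ci[, 2],
                   hi = ci[, 3], row.names = NULL)
  structure(list(draws = draws, ci = ci,
                 means = colMeans(draws[icer_cols], na.rm = TRUE),
                 n = n, seed = seed, input_names = names(overrides)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n, "iterations\n")
  cat("Varied inputs:", paste(x$input_names, collapse = ", "), "\n")
  df <- x$ci
  df[-1] <- lapply(df[-1], function(v) signif(v, 5))
  print(df, row.names = FALSE)
  invisible(x)
}

default_sd_map <- function(object) {
  cp <- object$config$costs$params
  eff <- object$effect
  psa <- object$config$psa
  base <- object$baseline
  sds <- stats::setNames(cp$monthly_sd * 12, cp$category)
  c(sds,
    lives_saved = sd_from_ci(eff$ci_low, eff$ci_high),
    min_wage = psa$wage_sd,
    committee_meetings = psa$meetings_cv * base$committee_meetings,
    children_per_creche = psa$children_sd)
}

#' Univariate (tornado) sensitivity analysis
#'
#' Varies each input by plus/minus one standard deviation, holding all
#' others at baseline, and reports the percent change in the chosen ICER,
#' ranked by absolute impact.
#'
#' @param object A fitted [creche_cea()] object.
#' @param sd_map Named numeric vector of 1-SD perturbations; defaults to the
#'   monthly-observation SDs (annualized) for cost categories, the CI-derived
#'   effect SD, and the configured wage/meeting/enrollment SDs.
#' @param outcome Engine outcome column. Default
#'   `"icer_life_societal_with_parents"`.
#' @return data.frame: `input`, `sd`, ICER at the low and high perturbation,
#'   percent changes, and `impact` (max absolute percent change), sorted
#'   decreasing.
#' @export
tornado <- function(object, sd_map = NULL,
                    outcome = "icer_life_societal_with_parents") {
  stopifnot(inherits(object, "creche_cea"))
  if (is.null(sd_map)) sd_map <- default_sd_map(object)
  base_val <- object$point[[outcome]]
  rows <- lapply(names(sd_map), function(nm) {
    b <- object$baseline[[nm]]
    if (is.null(b)) stop("unknown model parameter in sd_map: ", nm)
    vals <- vapply(c(b - sd_map[[nm]], b + sd_map[[nm]]), function(v) {
      cea_engine(object$baseline,
                 stats::setNames(list(v), nm))[[outcome]]
    }, numeric(1))
    data.frame(input = nm, sd = sd_map[[nm]],
               low = vals[1], high = vals[2],
               pct_low = 100 * (vals[1] - base_val) / abs(base_val),
               pct_high = 100 * (vals[2] - base_val) / abs(base_val),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$impact <- pmax(abs(out$pct_low), abs(out$pct_high))
  out[order(-out$impact), , drop = FALSE]
}

#' Proportional parameter sweep
#'
#' Evaluates an ICER along a grid of proportional changes to one parameter
#' (or to all program cost categories jointly via
#' `parameter = "program_cost"`), everything else held at baseline. The
#' response is exactly linear in cost parameters and hyperbolic in the
#' effect; a multiplier that zeroes the effect yields `NA` (undefined ICER).
#'
#' @param object A fitted [creche_cea()] object.
#' @param parameter Baseline parameter name, or `"program_cost"`.
#' @param multipliers Numeric grid. Default `seq(0.2, 1.8, by = 0.2)` (plus
#'   the baseline 1 if absent).
#' @param outcome Engine outcome column. Default `"icer_life_program"`.
#' @return data.frame: `multiplier`, `value` (parameter value), `outcome`.
#' @export
proportional_sweep <- function(object, parameter = "lives_saved",
                               multipliers = seq(0.2, 1.8, by = 0.2),
                               outcome = "icer_life_program") {
  stopifnot(inherits(object, "creche_cea"), is.finite(multipliers))
  if (!1 %in% multipliers) multipliers <- sort(c(multipliers, 1))
  base <- object$baseline
  if (parameter == "program_cost") {
    overrides <- lapply(stats::setNames(nm = base$cost_categories),
                        function(cc) base[[cc]] * multipliers)
    value <- multipliers * sum(unlist(base[base$cost_categories]))
  } else {
    b <- base[[parameter]]
    if (is.null(b)) stop("unknown model parameter: ", parameter)
    overrides <- stats::setNames(list(b * multipliers), parameter)
    value <- b * multipliers
  }
  res <- cea_engine(base, overrides)[[outcome]]
  data.frame(multiplier = multipliers, value = value, outcome = res)
}
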