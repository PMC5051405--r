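#' Parameter distribution for the probabilistic sensitivity analysis
#'
#' Describes how one field of a [country_parameters()] object is varied in
#' the Monte Carlo: a distribution family moment-matched to the field's
#' point value (mean) and a standard deviation. Families are restricted to
#' the field's support: `beta` only for proportion-type fields, `gamma` only
#' for non-negative quantities, `logistic` for effects that may in principle
#' take either sign (draws are truncated to the field's valid domain).
#' Vector fields (e.g. the five per-quintile costs) are varied element-wise
#' and independently.
#'
#' @param parameter Name of the `country_parameters` field.
#' @param family `"gamma"`, `"beta"` or `"logistic"`.
#' @param sd Absolute standard deviation (recycled across vector elements),
#'   or `NULL` to use `rel_sd`.
#' @param rel_sd Relative standard deviation: each element's sd is
#'   `rel_sd * |value|`. Ignored when `sd` is given.
#' @return Object of class `psa_spec`.
#' @export
psa_spec <- function(parameter, family = c("gamma", "beta", "logistic"),
                     sd = NULL, rel_sd = NULL) {
  family <- match.arg(family)
  if (!parameter %in% .psa_fields) {
    stop("unknown or non-varying parameter: '", parameter, "'", call. = FALSE)
  }
  if (family == "beta" && !parameter %in% .proportion_psa_fields) {
    stop("beta family is only valid for proportion-type parameters, not '",
         parameter, "'", call. = FALSE)
  }
  if (is.null(sd) && is.null(rel_sd)) {
    stop("spec for '", parameter, "' needs sd or rel_sd", call. = FALSE)
  }
  if (!is.null(sd) && (any(!is.finite(sd)) || any(sd < 0))) {
    stop("sd must be non-negative for '", parameter, "'", call. = FALSE)
  }
  out <- list(parameter = parameter, family = family, sd = sd, rel_sd = rel_sd)
  class(out) <- "psa_spec"
  out
}

.psa_fields <- c("mmr", "complicated_fraction", "rr_by_age",
                 "pregnant_by_age", "pregnant_by_quintile",
                 "usage_by_quintile", "oop_medical_by_quintile",
                 "oop_transport_by_quintile", "gdp_per_capita", "gini",
                 "education_effect", "education_cost_per_pupil")

.proportion_psa_fields <- c("complicated_fraction", "pregnant_by_age",
                            "pregnant_by_quintile", "usage_by_quintile",
                            "education_effect")

# valid domain to which trial draws are truncated, per field
.field_domain <- function(field) {
  if (field %in% .proportion_psa_fields) return(c(0, 1))
  if (field == "gini") return(c(1e-6, 1 - 1e-6))
  c(0, Inf)
}

#' Default PSA distribution set
#'
#' The parameters varied jointly by default are the maternal mortality
#' ratio, the age-specific relative risks of maternal mortality, all
#' out-of-pocket costs, the education cost per pupil (all gamma), and the
#' education effect (logistic with its configured standard error). Only the
#' education effect has a published standard error; every other sd defaults
#' to 10% of the point value and can be overridden by passing a custom spec
#' list to [run_psa()]. GDP per capita and the Gini index are held fixed by
#' default (the income model is re-derived per trial only when they appear
#' in the spec list).
#'
#' @param params A [country_parameters()] object.
#' @param rel_sd Default relative standard deviation for parameters without
#'   a published uncertainty (default 0.10).
#' @return List of [psa_spec()] objects.
#' @export
default_psa_specs <- function(params, rel_sd = 0.10) {
  stopifnot(inherits(params, "country_parameters"))
  list(
    psa_spec("mmr", "gamma", rel_sd = rel_sd),
    psa_spec("rr_by_age", "gamma", rel_sd = rel_sd),
    psa_spec("oop_medical_by_quintile", "gamma", rel_sd = rel_sd),
    psa_spec("oop_transport_by_quintile", "gamma", rel_sd = rel_sd),
    psa_spec("education_cost_per_pupil", "gamma", rel_sd = rel_sd),
    psa_spec("education_effect", "logistic", sd = params$education_effect_se)
  )
}

# n draws for one element: inverse-CDF transform of a shared uniform stream,
# so that matched seeds reuse the same uniforms whatever the sd
draw_element <- function(u, family, m, s, parameter) {
  if (s == 0 || (family != "logistic" && m == 0)) return(rep(m, length(u)))
  switch(family,
    gamma = stats::qgamma(u, shape = (m / s)^2, scale = s^2 / m),
    beta = {
      v <- s^2
      if (v >= m * (1 - m)) {
        stop("beta moment matching infeasible for parameter '", parameter,
             "': sd ", signif(s, 4), " too large for mean ", signif(m, 4),
             call. = FALSE)
      }
      t <- m * (1 - m) / v - 1
      stats::qbeta(u, shape1 = m * t, shape2 = (1 - m) * t)
    },
    logistic = stats::qlogis(u, location = m, scale = s * sqrt(3) / pi)
  )
}

# all outcomes the PSA (and reports) track, as a named numeric vector
ecea_outcomes <- function(params, income = build_income_model(params)) {
  deaths <- maternal_deaths(params)
  oop <- oop_costs(params)
  cat_res <- catastrophic_cases(params, income, method = "analytic")
  pol <- apply_policy(params, income)
  c(deaths_total = deaths$total,
    deaths_bottom_two_share = sum(deaths$shares[1:2]),
    oop_total = oop$total,
    oop_bottom_two_share = sum(oop$shares[1:2]),
    catastrophic_total = cat_res$cases_by_quintile$total,
    catastrophic_bottom_two_share = sum(cat_res$cases_by_quintile$shares[1:2]),
    catastrophic_incidence = cat_res$incidence,
    deaths_averted = pol$deaths_averted$total,
    oop_averted = pol$oop_averted$total,
    catastrophic_averted = pol$catastrophic_averted$total,
    education_cost = pol$education_cost)
}

#' Probabilistic sensitivity analysis
#'
#' Joint Monte Carlo over the configured parameter distributions: each trial
#' draws every varied parameter (moment-matched to its family), reruns the
#' full deterministic pipeline (deaths, out-of-pocket costs, catastrophic
#' cases, policy impact), and the 2.5th/97.5th percentiles across trials
#' form the 95% uncertainty range of each outcome. Percentiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#' Draws use an inverse-CDF transform of a seeded uniform stream, so results
#' are exactly reproducible per seed and widening every sd can only widen
#' the ranges at a matched seed.
#'
#' @param params A [country_parameters()] object (the point estimate).
#' @param specs List of [psa_spec()] objects; default [default_psa_specs()].
#' @param n_trials Number of Monte Carlo trials (default 1000, minimum 2).
#' @param seed Integer seed.
#' @return Object of class `ecea_psa`: `summary` (data frame with columns
#'   `outcome`, `point`, `lo`, `hi`), `draws` (trials x outcomes matrix),
#'   `n_trials`, `seed`.
#' @export
#' @examples
#' india <- load_country(ecea_fixture("india"))
#' run_psa(india, n_trials = 100, seed = 1)
run_psa <- function(params, specs = default_psa_specs(params),
                    n_trials = 1000, seed = 1) {
  stopifnot(inherits(params, "country_parameters"))
  if (length(n_trials) != 1L || !is.finite(n_trials) || n_trials < 2) {
    stop("n_trials must be at least 2", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (!is.list(specs) || length(specs) == 0L ||
      !all(vapply(specs, inherits, logical(1), "psa_spec"))) {
    stop("specs must be a non-empty list of psa_spec objects", call. = FALSE)
  }

  set.seed(as.integer(seed))
  draws_by_field <- list()
  for (sp in specs) {
    m <- params[[sp$parameter]]
    s <- if (!is.null(sp$sd)) rep_len(sp$sd, length(m)) else sp$rel_sd * abs(m)
    dom <- .field_domain(sp$parameter)
    mat <- matrix(NA_real_, n_trials, length(m))
    for (j in seq_along(m)) {
      u <- stats::runif(n_trials)
      mat[, j] <- pmin(pmax(draw_element(u, sp$family, m[j], s[j],
                                         sp$parameter), dom[1]), dom[2])
    }
    draws_by_field[[sp$parameter]] <- mat
  }

  vary_income <- any(c("gdp_per_capita", "gini") %in%
                       vapply(specs, `[[`, character(1), "parameter"))
  income <- build_income_model(params)
  point <- ecea_outcomes(params, income)

  draws <- matrix(NA_real_, n_trials, length(point),
                  dimnames = list(NULL, names(point)))
  for (i in seq_len(n_trials)) {
    p_i <- params
    for (field in names(draws_by_field)) p_i[[field]] <- draws_by_field[[field]][i, ]
    income_i <- if (vary_income) build_income_model(p_i) else income
    draws[i, ] <- ecea_outcomes(p_i, income_i)
  }

  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  out <- list(summary = data.frame(outcome = names(point),
                                   point = unname(point),
                                   lo = qs[1, ],
                                   hi = qs[2, ],
                                   row.names = NULL),
              draws = draws,
              n_trials = n_trials,
              seed = as.integer(seed))
  class(out) <- "ecea_psa"
  out
}

#' @export
print.ecea_psa <- function(x, digits = 4, ...) {
  cat(sprintf("<ecea_psa: %d trials, seed %d; 95%% uncertainty ranges>\n",
              x$n_trials, x$seed))
  s <- x$summary
  s[c("point", "lo", "hi")] <- lapply(s[c("point", "lo", "hi")], signif,
                                      digits = digits)
  print(s, row.names = FALSE)
  invisible(x)
}
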