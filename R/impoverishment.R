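#' Catastrophic health expenditure per income quintile
#'
#' Counts deliveries whose out-of-pocket payment (direct medical plus
#' transport) exceeds a fraction `threshold` of the woman's annual income.
#' Each complicated delivery that uses care is assigned an income drawn from
#' the calibrated gamma distribution conditional on the woman's quintile
#' band. The analytic method evaluates the condition in closed form:
#' OOP exceeds `threshold * income` exactly when income falls below
#' `OOP / threshold`, so the per-quintile count is the number of
#' cost-incurring deliveries times [prob_income_below()] at that cut-off.
#' The Monte Carlo method simulates one seeded income draw per delivery and
#' counts exceedances; it exists to validate the analytic path and converges
#' to it.
#'
#' @param params A [country_parameters()] object.
#' @param income An [build_income_model()] object; built from `params` when
#'   omitted.
#' @param threshold Catastrophic threshold as a fraction of annual income in
#'   (0, 1]; defaults to `params$catastrophic_threshold`.
#' @param method `"analytic"` (default, deterministic) or `"mc"`.
#' @param seed Integer seed for the Monte Carlo method.
#' @param denominator Denominator convention for the incidence proportion:
#'   `"quintile"` (default) divides by the pregnant-adolescent count implied
#'   by the per-quintile percentages, `sum((N/5) * pregnant_by_quintile)`;
#'   `"age"` divides by the per-age total used for the death computation.
#' @return Object of class `impoverishment_result`: `cases_by_quintile`
#'   (a [quintile_outcomes()]), `threshold`, `method`, `incidence`,
#'   `denominator`.
#' @export
#' @examples
#' india <- load_country(ecea_fixture("india"))
#' catastrophic_cases(india)
catastrophic_cases <- function(params,
                               income = build_income_model(params),
                               threshold = params$catastrophic_threshold,
                               method = c("analytic", "mc"),
                               seed = NULL,
                               denominator = c("quintile", "age")) {
  stopifnot(inherits(params, "country_parameters"),
            inherits(income, "income_model"))
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  ledger <- build_pregnancy_ledger(params)
  at_risk <- ledger$oop_incurring_per_quintile
  unit_cost <- params$oop_medical_by_quintile + params$oop_transport_by_quintile
  cutoffs <- unit_cost / threshold  # income below this => catastrophic

  if (method == "analytic") {
    p_cat <- vapply(1:5, function(q) prob_income_below(income, cutoffs[q], q),
                    numeric(1))
    cases <- at_risk * p_cat
  } else {
    if (!is.null(seed)) set.seed(seed)
    cases <- vapply(1:5, function(q) {
      n_q <- round(at_risk[q])
      if (n_q == 0) return(0)
      draws <- sample_incomes(income, n_q, quintile = q)
      sum(unit_cost[q] > threshold * draws)
    }, numeric(1))
  }

  denom <- switch(denominator,
                  quintile = sum(params$population_15_19 / 5 *
                                   params$pregnant_by_quintile),
                  age = ledger$total)
  res <- list(cases_by_quintile = quintile_outcomes(cases, units = "cases"),
              threshold = threshold,
              method = method,
              incidence = if (denom > 0) sum(cases) / denom else NA_real_,
              denominator = denominator)
  class(res) <- "impoverishment_result"
  attr(res, "ledger") <- ledger
  res
}

#' Poverty headcount attributable to out-of-pocket payments
#'
#' Counts deliveries where the woman's income was at or above the poverty
#' line before paying and falls below it after paying the quintile's
#' out-of-pocket cost: income in `[line, line + OOP)`. The analytic method
#' uses the conditional gamma CDF on that band within each quintile; the
#' Monte Carlo method uses seeded conditional income draws.
#'
#' @inheritParams catastrophic_cases
#' @param poverty_line Annual income poverty line, US$2014, > 0; defaults to
#'   `params$poverty_line`.
#' @return An `impoverishment_result` with `threshold = NA` and an extra
#'   field `poverty_line`.
#' @export
poverty_headcount <- function(params,
                              income = build_income_model(params),
                              poverty_line = params$poverty_line,
                              method = c("analytic", "mc"),
                              seed = NULL,
                              denominator = c("quintile", "age")) {
  stopifnot(inherits(params, "country_parameters"),
            inherits(income, "income_model"))
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  if (is.null(poverty_line)) {
    stop("no poverty line configured: set params$poverty_line or pass ",
         "poverty_line explicitly", call. = FALSE)
  }
  if (length(poverty_line) != 1L || !is.finite(poverty_line) ||
      poverty_line < 0) {
    stop("poverty_line must be a single non-negative number", call. = FALSE)
  }
  ledger <- build_pregnancy_ledger(params)
  at_risk <- ledger$oop_incurring_per_quintile
  unit_cost <- params$oop_medical_by_quintile + params$oop_transport_by_quintile

  if (poverty_line == 0) {
    # poverty means income strictly below the line; a zero line defines an
    # empty poverty set, so nobody can be pushed into it
    cases <- rep(0, 5)
  } else if (method == "analytic") {
    cases <- vapply(1:5, function(q) {
      band <- quintile_band(income, q)
      lo <- max(band[["lo"]], poverty_line)
      hi <- min(band[["hi"]], poverty_line + unit_cost[q])
      if (hi <= lo) return(0)
      p <- (stats::pgamma(hi, shape = income$shape, scale = income$scale) -
              stats::pgamma(lo, shape = income$shape, scale = income$scale)) / 0.2
      at_risk[q] * min(1, max(0, p))
    }, numeric(1))
  } else {
    if (!is.null(seed)) set.seed(seed)
    cases <- vapply(1:5, function(q) {
      n_q <- round(at_risk[q])
      if (n_q == 0) return(0)
      draws <- sample_incomes(income, n_q, quintile = q)
      sum(draws >= poverty_line & draws - unit_cost[q] < poverty_line)
    }, numeric(1))
  }

  denom <- switch(denominator,
                  quintile = sum(params$population_15_19 / 5 *
                                   params$pregnant_by_quintile),
                  age = ledger$total)
  res <- list(cases_by_quintile = quintile_outcomes(cases, units = "cases"),
              threshold = NA_real_,
              method = method,
              incidence = if (denom > 0) sum(cases) / denom else NA_real_,
              denominator = denominator,
              poverty_line = poverty_line)
  class(res) <- "impoverishment_result"
  attr(res, "ledger") <- ledger
  res
}

#' Catastrophic-case counts across a set of thresholds
#'
#' Re-runs [catastrophic_cases()] at each threshold (e.g. 10%, 20%, 40% of
#' income). Totals are monotone non-increasing in the threshold.
#'
#' @inheritParams catastrophic_cases
#' @param thresholds Non-empty numeric vector of thresholds in (0, 1].
#' @return A list of `impoverishment_result`, one per threshold, named by
#'   threshold.
#' @export
threshold_sweep <- function(params,
                            income = build_income_model(params),
                            thresholds = c(0.10, 0.20, 0.40),
                            method = c("analytic", "mc"),
                            seed = NULL) {
  if (length(thresholds) == 0L) {
    stop("thresholds must be a non-empty vector", call. = FALSE)
  }
  method <- match.arg(method)
  out <- lapply(thresholds, function(tau) {
    catastrophic_cases(params, income, threshold = tau, method = method,
                       seed = seed)
  })
  names(out) <- format(thresholds, trim = TRUE)
  out
}

#' @export
print.impoverishment_result <- function(x, ...) {
  label <- if (is.na(x$threshold)) {
    sprintf("poverty headcount, line $%g", x$poverty_line)
  } else {
    sprintf("catastrophic expenditure, threshold %g%% of income",
            100 * x$threshold)
  }
  cat(sprintf("<impoverishment_result: %s (%s)>\n", label, x$method))
  print(x$cases_by_quintile, ...)
  cat(sprintf("  incidence among pregnant adolescents: %.3g%% (%s denominator)\n",
              100 * x$incidence, x$denominator))
  invisible(x)
}
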