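#' Simulate a cross-country education/pregnancy dataset
#'
#' Generates country-level observations of mean years of female education
#' against the adolescent pregnancy rate, with a known linear effect, for
#' exercising and calibrating [fit_education_effect()]. Education years are
#' drawn uniformly on `years_range`; rates follow
#' `intercept + beta * years + noise` with
#' `beta = -true_relative_reduction * mean_rate` and the intercept anchored
#' so the rate at the midpoint of `years_range` equals `mean_rate`. Rates
#' are clipped to `[0, 1]` (the defaults make clipping negligible; a
#' configuration that clips every row is rejected as degenerate).
#'
#' @param n_countries Number of countries, >= 3 (default 80).
#' @param true_relative_reduction Generating relative reduction per year of
#'   education, in `[0, 1)` (default 0.18).
#' @param mean_rate Adolescent pregnancy rate at the midpoint education
#'   level (default 0.15).
#' @param noise_sd Residual standard deviation on the rate scale
#'   (default 0.04, giving a moderate cross-country R^2).
#' @param years_range Range of mean education years (default `c(3, 9)`).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream
#'   (the usual choice inside a larger seeded simulation).
#' @return Data frame with columns `country`, `education_years`,
#'   `pregnancy_rate`; attributes `truth` (list with `slope`, `intercept`,
#'   `relative_reduction`, `mean_rate`), `noise_sd`, `seed`.
#' @export
#' @examples
#' d <- generate_education_dataset(seed = 7)
#' fit_education_effect(d)
generate_education_dataset <- function(n_countries = 80,
                                       true_relative_reduction = 0.18,
                                       mean_rate = 0.15,
                                       noise_sd = 0.04,
                                       years_range = c(3, 9),
                                       seed = 1) {
  if (length(n_countries) != 1L || !is.finite(n_countries) || n_countries < 3) {
    stop("n_countries must be at least 3", call. = FALSE)
  }
  if (true_relative_reduction < 0 || true_relative_reduction >= 1) {
    stop("true_relative_reduction must lie in [0, 1)", call. = FALSE)
  }
  n_countries <- as.integer(n_countries)
  if (!is.null(seed)) set.seed(as.integer(seed))
  years <- stats::runif(n_countries, years_range[1], years_range[2])
  slope <- -true_relative_reduction * mean_rate
  intercept <- mean_rate - slope * mean(years_range)
  rate_raw <- intercept + slope * years + stats::rnorm(n_countries, 0, noise_sd)
  rate <- pmin(1, pmax(0, rate_raw))
  if (all(rate == 0) || all(rate == 1)) {
    stop("degenerate configuration: every generated rate was clipped",
         call. = FALSE)
  }
  out <- data.frame(country = sprintf("C%03d", seq_len(n_countries)),
                    education_years = years,
                    pregnancy_rate = rate)
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             relative_reduction = true_relative_reduction,
                             mean_rate = mean_rate)
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  out
}

#' Generate a random valid country parameter set
#'
#' Draws a parameter set in realistic low- and middle-income ranges
#' (population 15-19 between 1e5 and 1e8, MMR 20-900 per 100 000, rising
#' care usage and falling pregnancy prevalence across quintiles, GDP per
#' capita $200-$20 000, Gini 0.25-0.60). Every invariant of
#' [country_parameters()] holds by construction; intended for
#' property-style testing.
#'
#' @param seed Integer seed.
#' @return A validated [country_parameters()] object.
#' @export
#' @examples
#' generate_country(seed = 42)$name
generate_country <- function(seed = 1) {
  set.seed(as.integer(seed))
  runif1 <- function(lo, hi) stats::runif(1, lo, hi)
  sorted5 <- function(lo, hi, decreasing = FALSE) {
    sort(stats::runif(5, lo, hi), decreasing = decreasing)
  }
  country_parameters(
    name = sprintf("synthetic-%d", as.integer(seed)),
    population_15_19 = round(10^runif1(5, 8)),
    mmr = runif1(20, 900),
    complicated_fraction = runif1(0.05, 0.30),
    rr_by_age = c(runif1(1, 6), rep(1, 4)),
    pregnant_by_age = sorted5(0.005, 0.25),
    pregnant_by_quintile = sorted5(0.02, 0.50, decreasing = TRUE),
    usage_by_quintile = sorted5(0.05, 0.95),
    oop_medical_by_quintile = sorted5(10, 250),
    oop_transport_by_quintile = sorted5(1, 25),
    gdp_per_capita = round(10^runif1(log10(200), log10(20000))),
    gini = runif1(0.25, 0.60),
    education_cost_per_pupil = runif1(20, 500),
    education_effect = runif1(0.05, 0.30),
    education_effect_se = runif1(0.005, 0.05)
  )
}
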