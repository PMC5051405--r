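#' Gini index of a gamma income distribution
#'
#' For a gamma distribution with shape `k` the Gini index has the closed form
#' \deqn{G(k) = \Gamma(k + 1/2) / (\sqrt{\pi}\, \Gamma(k + 1)),}
#' independent of the scale parameter. `G` decreases from 1 (as `k` tends to
#' 0, extreme inequality) to 0 (as `k` grows, equal incomes); `k = 1`, the
#' exponential distribution, gives exactly 1/2.
#'
#' @param shape Gamma shape parameter(s), > 0.
#' @return Gini index in (0, 1), same length as `shape`.
#' @export
gamma_gini <- function(shape) {
  if (any(shape <= 0)) stop("shape must be > 0", call. = FALSE)
  exp(lgamma(shape + 0.5) - lgamma(shape + 1)) / sqrt(pi)
}

#' Invert the gamma Gini formula
#'
#' Finds the gamma shape `k` whose Gini index [gamma_gini()] equals the
#' input, by root bracketing on `k` in `[1e-3, 1e3]`. The mapping is strictly
#' monotone so the root is unique.
#'
#' @param gini Target Gini index, strictly inside (0, 1).
#' @param tol Convergence tolerance on `k` (default 1e-12).
#' @return The gamma shape parameter.
#' @export
#' @examples
#' gini_to_shape(0.5)  # exponential: shape 1
gini_to_shape <- function(gini, tol = 1e-12) {
  if (length(gini) != 1L || !is.finite(gini) || gini <= 0 || gini >= 1) {
    stop("gini must be a single value strictly inside (0, 1)", call. = FALSE)
  }
  lo <- 1e-3
  hi <- 1e3
  if (gini >= gamma_gini(lo) || gini <= gamma_gini(hi)) {
    stop("gini outside the invertible bracket [", signif(gamma_gini(hi), 3),
         ", ", signif(gamma_gini(lo), 3), "]", call. = FALSE)
  }
  stats::uniroot(function(k) gamma_gini(k) - gini,
                 interval = c(lo, hi), tol = tol)$root
}

#' Calibrate the income distribution of a country
#'
#' Builds the gamma income model used throughout the analysis: the shape is
#' chosen so the distribution's Gini index equals the country's, and the
#' scale so its mean equals GDP per capita. Quintile boundaries are the
#' population 20/40/60/80th percentile incomes; quintile membership is
#' defined by these population quantiles rather than by re-ranking any finite
#' sample, so it is deterministic and sample-size free.
#'
#' @param params A [country_parameters()] object (only `gdp_per_capita` and
#'   `gini` are used).
#' @return An object of class `income_model` with fields `shape`, `scale`
#'   (US$2014), `quintile_bounds` (4 interior boundaries, US$2014), and the
#'   calibration anchors `mean` and `gini`.
#' @export
#' @examples
#' m <- build_income_model(load_country(ecea_fixture("india")))
#' m$shape * m$scale  # 1596, the mean income
build_income_model <- function(params) {
  stopifnot(inherits(params, "country_parameters"))
  shape <- gini_to_shape(params$gini)
  scale <- params$gdp_per_capita / shape
  model <- list(
    shape = shape,
    scale = scale,
    quintile_bounds = stats::qgamma(c(0.2, 0.4, 0.6, 0.8), shape = shape,
                                    scale = scale),
    mean = params$gdp_per_capita,
    gini = params$gini
  )
  class(model) <- "income_model"
  model
}

# income band [lo, hi) of quintile q under the population quantile rule
quintile_band <- function(model, quintile) {
  stopifnot(inherits(model, "income_model"),
            quintile %in% 1:5)
  bounds <- c(0, model$quintile_bounds, Inf)
  c(lo = bounds[quintile], hi = bounds[quintile + 1L])
}

#' Conditional probability of a low income within a quintile
#'
#' Probability that an individual's annual income falls below `threshold`,
#' given that the individual belongs to income quintile `quintile`:
#' \eqn{(F(\min(t, hi)) - F(lo))^+ / 0.2} where `F` is the gamma CDF and
#' `(lo, hi)` the quintile's income band.
#'
#' @param model An [build_income_model()] object.
#' @param threshold Income threshold, US$2014, >= 0. Vectorized.
#' @param quintile Quintile index 1 (poorest) to 5 (richest).
#' @return Probability in `[0, 1]`, same length as `threshold`.
#' @export
prob_income_below <- function(model, threshold, quintile) {
  stopifnot(all(threshold >= 0))
  band <- quintile_band(model, quintile)
  upper <- stats::pgamma(pmin(threshold, band[["hi"]]), shape = model$shape,
                         scale = model$scale)
  lower <- stats::pgamma(band[["lo"]], shape = model$shape, scale = model$scale)
  pmin(1, pmax(0, (upper - lower) / 0.2))
}

#' Sample annual incomes
#'
#' Draws incomes from the calibrated gamma distribution, optionally
#' conditioned on a quintile band (via inverse-CDF sampling of a uniform
#' restricted to the band's probability interval). Reproducible for a fixed
#' seed.
#'
#' @param model An [build_income_model()] object.
#' @param n Number of draws, > 0.
#' @param seed Optional integer seed; when supplied, the RNG state is set
#'   before sampling.
#' @param quintile Optional quintile index 1..5; when supplied, draws are
#'   from the conditional distribution within that quintile's income band.
#' @return Numeric vector of `n` incomes (US$2014).
#' @export
sample_incomes <- function(model, n, seed = NULL, quintile = NULL) {
  stopifnot(inherits(model, "income_model"))
  if (length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("n must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(quintile)) {
    return(stats::rgamma(n, shape = model$shape, scale = model$scale))
  }
  p <- 0.2 * c(quintile - 1L, quintile)
  u <- stats::runif(n, p[1L], p[2L])
  stats::qgamma(u, shape = model$shape, scale = model$scale)
}

#' @export
print.income_model <- function(x, ...) {
  cat(sprintf("<income_model: gamma(shape = %.6g, scale = %.6g)>\n",
              x$shape, x$scale))
  cat(sprintf("  mean $%.6g, Gini %.4g\n", x$mean, x$gini))
  cat(sprintf("  quintile bounds ($): %s\n",
              paste(format(round(x$quintile_bounds, 2), trim = TRUE),
                    collapse = ", ")))
  invisible(x)
}
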