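# Oracle values frozen from an independent Lorenz-curve computation:
# G(k) = 1 - 2 * integral_0^1 L(p) dp with L(p) = F_{k+1}(F_k^{-1}(p)),
# integrated numerically (rel.tol 1e-12) and bisected on k (200 halvings
# of [0.5, 20]). The closed form used by the package never enters.
K_GINI_034 <- 2.4923502091
K_GINI_032 <- 2.8485499553

# Conditional-probability oracle frozen from 1e7 seeded gamma draws
# (seed 20160923): empirical fraction of quintile-1 incomes below $660
# under the India model; binomial SE 2.81e-4.
P660_Q1_MC <- 0.804002
P660_Q1_3SE <- 3 * 0.000281

test_that("the gamma Gini closed form and its inverse agree with the Lorenz oracle", {
  expect_equal(gamma_gini(1), 0.5)  # exponential distribution, analytic
  expect_equal(gini_to_shape(0.5), 1, tolerance = 1e-8)
  expect_equal(gini_to_shape(0.34), K_GINI_034, tolerance = 1e-7)
  expect_equal(gini_to_shape(0.32), K_GINI_032, tolerance = 1e-7)
})

test_that("gini_to_shape inverts the closed form across the working range", {
  for (g in seq(0.05, 0.95, by = 0.05)) {
    expect_lt(abs(gamma_gini(gini_to_shape(g)) - g), 1e-10)
  }
  expect_error(gini_to_shape(0), "gini")
  expect_error(gini_to_shape(1), "gini")
  expect_error(gini_to_shape(-0.2), "gini")
  expect_error(gamma_gini(0), "shape")
})

test_that("the calibrated income model matches its anchors", {
  for (params in list(india_params(), niger_params())) {
    m <- build_income_model(params)
    expect_equal(m$shape * m$scale, params$gdp_per_capita,
                 tolerance = 1e-12)
    expect_lt(abs(gamma_gini(m$shape) - params$gini), 1e-10)
    expect_true(all(diff(m$quintile_bounds) > 0))
  }
  # near-equal incomes: quintile boundaries collapse toward the mean
  p <- india_params()
  p$gini <- 0.02
  m <- build_income_model(p)
  expect_true(all(abs(m$quintile_bounds / p$gdp_per_capita - 1) < 0.05))
})

test_that("conditional probabilities behave like a conditional CDF", {
  m <- build_income_model(india_params())
  for (q in 1:5) expect_equal(prob_income_below(m, 0, q), 0)
  # whole poorest band lies below a threshold above its upper bound
  expect_equal(prob_income_below(m, m$quintile_bounds[1] + 1, 1), 1)
  # monotone in the threshold, each quintile
  grid <- seq(0, 6000, by = 250)
  for (q in 1:5) {
    p <- vapply(grid, prob_income_below, numeric(1), model = m, quintile = q)
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0 & p <= 1))
  }
  # quintile-weighted sum recovers the unconditional CDF
  for (thr in c(100, 660, 1596, 4000)) {
    weighted <- 0.2 * sum(vapply(1:5, prob_income_below, numeric(1),
                                 model = m, threshold = thr))
    expect_equal(weighted, pgamma(thr, shape = m$shape, scale = m$scale),
                 tolerance = 1e-12)
  }
  expect_equal(prob_income_below(m, 660, 1), P660_Q1_MC,
               tolerance = P660_Q1_3SE / P660_Q1_MC)
})

test_that("seeded sampling reproduces the calibration empirically", {
  india <- build_income_model(india_params())
  x <- sample_incomes(india, 1e6, seed = 11)
  expect_identical(x, sample_incomes(india, 1e6, seed = 11))
  expect_lt(abs(mean(x) / 1596 - 1), 0.01)

  niger <- build_income_model(niger_params())
  y <- sort(sample_incomes(niger, 1e6, seed = 12))
  n <- length(y)
  empirical_gini <- sum((2 * seq_len(n) - n - 1) * y) / (n^2 * mean(y))
  expect_lt(abs(empirical_gini - 0.32), 0.005)

  # conditional draws stay inside their band and match the analytic
  # conditional probability within 3 binomial SEs
  band <- c(0, india$quintile_bounds)[2:3]
  z <- sample_incomes(india, 2e5, seed = 13, quintile = 2)
  expect_true(all(z >= band[1] & z <= band[2]))
  p_hat <- mean(z < 900)
  p_true <- prob_income_below(india, 900, 2)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 2e5))

  expect_error(sample_incomes(india, 0), "positive")
  expect_error(sample_incomes(india, -5), "positive")
})
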