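test_that("noise-free synthetic data yields exact slope recovery", {
  d <- generate_education_dataset(n_countries = 40, noise_sd = 0, seed = 2)
  ef <- suppressWarnings(fit_education_effect(d))  # perfect-fit lm notice
  truth <- attr(d, "truth")
  fit <- attr(ef, "fit")
  expect_equal(unname(coef(fit)["education_years"]), truth$slope,
               tolerance = 1e-12)
  # the elasticity rescaling uses the realized mean rate, so the recovered
  # relative reduction matches the generating one closely but not exactly
  expect_equal(ef$relative_reduction, 0.18, tolerance = 0.02)
  expect_identical(ef$source, "fitted")
})

test_that("noisy recovery is within two standard errors and flat data gives zero", {
  d <- generate_education_dataset(seed = 3)
  ef <- fit_education_effect(d)
  expect_lt(abs(ef$relative_reduction - 0.18), 2 * ef$se)

  flat <- data.frame(education_years = 1:10, pregnancy_rate = rep(0.2, 10))
  expect_equal(suppressWarnings(fit_education_effect(flat))$relative_reduction,
               0)

  degenerate <- data.frame(education_years = rep(5, 10),
                           pregnancy_rate = runif(10))
  expect_error(fit_education_effect(degenerate), "variance")
  expect_error(fit_education_effect(data.frame(education_years = 1:2,
                                               pregnancy_rate = c(0.1, 0.2))),
               "at least 3")
  expect_error(fit_education_effect(data.frame(x = 1:5)), "columns")
})

test_that("the education cost is cohort size times unit cost", {
  expect_equal(education_cost(niger_params()), 1021000 / 5 * 72)   # $14.7M
  expect_equal(education_cost(india_params()), 58400000 / 5 * 258) # $3013M
  p <- niger_params()
  p$education_cost_per_pupil <- 0
  expect_equal(education_cost(p), 0)
})

test_that("averted outcomes are exactly linear in the effect size", {
  india <- india_params()
  income <- build_income_model(india)
  base <- apply_policy(india, income, effect = education_effect(0.18, 0.02))

  # every averted quantity equals e times its baseline counterpart
  expect_equal(base$deaths_averted$values,
               0.18 * maternal_deaths(india)$values, tolerance = 1e-9)
  expect_equal(base$oop_averted$values, 0.18 * oop_costs(india)$values,
               tolerance = 1e-9)
  expect_equal(base$catastrophic_averted$values,
               0.18 * catastrophic_cases(india, income)$cases_by_quintile$values,
               tolerance = 1e-9)

  for (e in seq(0.05, 0.30, by = 0.05)) {
    pol <- apply_policy(india, income, effect = education_effect(e, 0))
    expect_equal(pol$deaths_averted$total / e,
                 base$deaths_averted$total / 0.18, tolerance = 1e-9)
    expect_equal(pol$catastrophic_averted$total / e,
                 base$catastrophic_averted$total / 0.18, tolerance = 1e-9)
  }

  null <- apply_policy(india, income, effect = education_effect(0, 0))
  expect_equal(null$deaths_averted$total, 0)
  expect_equal(null$oop_averted$total, 0)
  expect_equal(null$catastrophic_averted$total, 0)
  expect_equal(null$education_cost, base$education_cost)
})

test_that("discounting strictly shrinks benefits and costs", {
  for (fixture in c("india", "niger")) {
    params <- load_country(ecea_fixture(fixture))
    income <- build_income_model(params)
    undisc <- apply_policy(params, income, discount = FALSE)
    disc <- apply_policy(params, income, discount = TRUE)
    expect_lt(disc$deaths_averted$total, undisc$deaths_averted$total)
    expect_lt(disc$oop_averted$total, undisc$oop_averted$total)
    expect_lt(disc$catastrophic_averted$total,
              undisc$catastrophic_averted$total)
    expect_lt(disc$education_cost, undisc$education_cost)
    # quintile shares are unaffected by a common discount factor
    expect_equal(disc$deaths_averted$shares, undisc$deaths_averted$shares)
  }
})

test_that("effect sensitivity rescales all averted quantities proportionally", {
  india <- india_params()
  income <- build_income_model(india)
  tab <- effect_sensitivity(india, income, effects = list(0.18, 0.11, 0.09))
  expect_equal(tab$relative_change, c(0, 11 / 18 - 1, -0.5), tolerance = 1e-9)
  expect_equal(tab$oop_averted[2] / tab$oop_averted[1], 11 / 18,
               tolerance = 1e-9)
  expect_equal(tab$catastrophic_averted[3] / tab$catastrophic_averted[1], 0.5,
               tolerance = 1e-9)
  same <- effect_sensitivity(india, income, effects = list(0.18, 0.18))
  expect_equal(same$relative_change[2], 0)
  expect_error(effect_sensitivity(india, income, effects = list()),
               "non-empty")
})
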