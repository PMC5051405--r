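test_that("catastrophic counting has the right limits", {
  india <- india_params()
  income <- build_income_model(india)

  # out-of-pocket costs tiny relative to income, threshold 100%: no cases
  cheap <- india
  cheap$oop_medical_by_quintile <- rep(0.01, 5)
  cheap$oop_transport_by_quintile <- rep(0, 5)
  res <- catastrophic_cases(cheap, income, threshold = 1)
  expect_equal(res$cases_by_quintile$total, 0, tolerance = 1e-6)

  # vanishing threshold: every cost-incurring delivery is catastrophic
  res0 <- catastrophic_cases(india, income, threshold = 1e-9)
  ledger <- build_pregnancy_ledger(india)
  expect_equal(res0$cases_by_quintile$total,
               sum(ledger$oop_incurring_per_quintile))

  # cases can never exceed the cost-incurring deliveries, quintile-wise
  res10 <- catastrophic_cases(india, income)
  expect_true(all(res10$cases_by_quintile$values <=
                    ledger$oop_incurring_per_quintile + 1e-9))
  expect_gte(res10$incidence, 0)
  expect_lte(res10$incidence, 1)

  expect_error(catastrophic_cases(india, income, threshold = 0), "threshold")
  expect_error(catastrophic_cases(india, income, threshold = 2), "threshold")
  expect_error(catastrophic_cases(india, income, method = "bogus"))
})

test_that("analytic and Monte Carlo catastrophic counts agree within 3 binomial SEs", {
  for (fixture in c("india", "niger")) {
    params <- load_country(ecea_fixture(fixture))
    income <- build_income_model(params)
    analytic <- catastrophic_cases(params, income, method = "analytic")
    mc <- catastrophic_cases(params, income, method = "mc", seed = 7)
    expect_lt(abs(analytic$cases_by_quintile$total -
                    mc$cases_by_quintile$total),
              max(mc_3se(analytic), 1), label = fixture)
    # determinism of the seeded Monte Carlo path
    mc2 <- catastrophic_cases(params, income, method = "mc", seed = 7)
    expect_identical(mc$cases_by_quintile$values, mc2$cases_by_quintile$values)
  }
})

test_that("catastrophic counts move the right way with costs, threshold and income", {
  base_p <- niger_params()
  income <- build_income_model(base_p)
  base <- catastrophic_cases(base_p, income)

  costly <- base_p
  costly$oop_medical_by_quintile <- costly$oop_medical_by_quintile * 2
  expect_true(all(catastrophic_cases(costly, income)$cases_by_quintile$values >=
                    base$cases_by_quintile$values - 1e-9))

  richer <- base_p
  richer$gdp_per_capita <- base_p$gdp_per_capita * 3
  expect_true(all(catastrophic_cases(richer)$cases_by_quintile$values <=
                    base$cases_by_quintile$values + 1e-9))

  sweep <- threshold_sweep(base_p, income, thresholds = c(0.10, 0.20, 0.40))
  totals <- vapply(sweep, function(x) x$cases_by_quintile$total, numeric(1))
  expect_true(all(diff(totals) <= 1e-9))
  single <- threshold_sweep(base_p, income, thresholds = 0.10)
  expect_equal(single[[1]]$cases_by_quintile$values,
               base$cases_by_quintile$values)
  expect_error(threshold_sweep(base_p, income, thresholds = numeric(0)),
               "non-empty")
})

test_that("incidence uses the documented pregnant-adolescent denominators", {
  niger <- niger_params()
  res_q <- catastrophic_cases(niger, denominator = "quintile")
  denom_q <- sum(niger$population_15_19 / 5 * niger$pregnant_by_quintile)
  expect_equal(res_q$incidence, res_q$cases_by_quintile$total / denom_q)
  res_a <- catastrophic_cases(niger, denominator = "age")
  expect_equal(res_a$incidence,
               res_a$cases_by_quintile$total / build_pregnancy_ledger(niger)$total)
})

test_that("the poverty headcount counts only line-crossers", {
  niger <- niger_params()
  income <- build_income_model(niger)

  expect_equal(poverty_headcount(niger, income, poverty_line = 0)$
                 cases_by_quintile$total, 0)
  # a line far above every income: nobody was above it to begin with
  expect_equal(poverty_headcount(niger, income, poverty_line = 1e9)$
                 cases_by_quintile$total, 0, tolerance = 1e-6)
  # unset line is a configuration error
  expect_error(poverty_headcount(niger, income), "poverty line")

  analytic <- poverty_headcount(niger, income, poverty_line = 200)
  mc <- poverty_headcount(niger, income, poverty_line = 200, method = "mc",
                          seed = 5)
  expect_lt(abs(analytic$cases_by_quintile$total -
                  mc$cases_by_quintile$total),
            max(mc_3se(analytic), 1))
  expect_true(all(analytic$cases_by_quintile$values <=
                    build_pregnancy_ledger(niger)$oop_incurring_per_quintile +
                    1e-9))
})
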