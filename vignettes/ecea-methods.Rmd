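---
title: "Modelling adolescent maternal deaths and medical impoverishment per income quintile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adolescent maternal deaths and medical impoverishment per income quintile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eceamat)
```

## The problem

Adolescent girls (15–19) in low- and middle-income countries face elevated
maternal mortality and, when a delivery is complicated, out-of-pocket (OOP)
payments that can be catastrophic relative to their income. An extended
cost-effectiveness analysis (ECEA) asks not only *how much* mortality and
spending a condition causes, but *who bears it*: the package decomposes
three annual outcomes across income quintiles Q1 (poorest) to Q5 (richest) —

1. adolescent maternal deaths,
2. OOP expenditure on complicated deliveries (direct medical plus transport),
3. cases of catastrophic health expenditure (OOP above a fraction τ of
   annual income; default τ = 10%, with 20%/40% sensitivity variants and a
   poverty-headcount alternative),

and evaluates a policy counterfactual: raising mean female education by one
year, which multiplies adolescent pregnancy rates by $1 - e$ with
$e = 18\%$ (SE 2%) per year of schooling, against the programme cost of one
additional year of primary education for the entering cohort.

Two country parameter sets ship as fixtures (`ecea_fixture("india")`,
`ecea_fixture("niger")`), chosen as the canonical high-burden contrast: a
large middle-income country with many maternal deaths versus a low-income
country with the world's highest fertility.

## The model

### Pregnancies, deaths, costs

Each single year of age holds one fifth of the 15–19 population $N$.
With $\pi_a$ the fraction pregnant at age $a$ and $r_a$ the relative risk
of maternal death versus women 20–24, annual deaths are

$$D = \sum_{a=15}^{19} \frac{N}{5}\,\pi_a \, r_a \, \frac{\mathrm{MMR}}{10^5},$$

treating each pregnancy carried to term as the live-birth denominator and
applying the published 15–49 MMR directly at the non-elevated ages. No
renormalisation holds the all-age MMR fixed under the age-specific risks;
with the shipped inputs this unrescaled reading reproduces the published
country totals, which is why it was chosen.

The two pregnancy parameterisations in the inputs — per-age percentages
(mean ≈ 6% in India) and per-quintile percentages (mean ≈ 12% in India) —
come from different survey instruments and are not mutually consistent as
absolute rates. The package reconciles them by convention: **per-age
percentages set the total; per-quintile percentages act only as normalised
shares** splitting that total across quintiles. This reproduces both the
published death totals and the published bottom-two-quintile shares (60%
in India, 49% in Niger, which are analytically the normalised share sums).
The alternative absolute reading is available via
`build_pregnancy_ledger(..., quintile_rule = "absolute")` for sensitivity
exploration. Mortality risk conditional on pregnancy is assumed independent
of income, so the equity decomposition of deaths *is* the pregnancy-share
vector.

A fixed fraction κ = 15% of pregnancies end in a complicated delivery.
Only complicated deliveries with skilled birth attendance (coverage $u_q$)
incur OOP costs $c_q + t_q$ (medical plus transport); women who forgo care
pay nothing and are structurally excluded from the impoverishment count —
a known limitation of the catastrophic-expenditure metric, inherited
deliberately. Deaths do not reduce the cost base.

### The income model

Annual individual income follows a gamma distribution calibrated to two
country anchors: the mean equals GDP per capita, and the Gini index matches
the country's. For a gamma with shape $k$ the Gini has the closed form

$$G(k) = \frac{\Gamma(k + 1/2)}{\sqrt{\pi}\,\Gamma(k+1)},$$

strictly decreasing in $k$, so calibration is the one-dimensional root
finding problem solved by `gini_to_shape()` (Brent bracketing on
$k \in [10^{-3}, 10^3]$, tolerance $10^{-12}$; the bracket covers Gini
values from about 0.018 to 0.999, far beyond any national income Gini).
The scale is then $\theta = Y/k$. This mean-matched gamma is the standard
parametric income model in the health-financing literature; whether the
original analyses matched the mean or the median is not documented, and
the mean is the convention adopted here. Income is annual individual
income with no household equivalisation.

Quintile membership is defined by the population quantiles at
20/40/60/80% — not by re-ranking a finite sample — so all conditional
quantities are deterministic and sample-size free. The catastrophic
condition $\mathrm{OOP} > \tau \cdot \mathrm{income}$ is equivalent to
income below $\mathrm{OOP}/\tau$, so the analytic per-quintile count is

$$K_q = n_q \cdot \frac{(F(\min(c_q^{tot}/\tau,\ hi_q)) - F(lo_q))^+}{0.2},$$

with $n_q$ the cost-incurring deliveries in quintile $q$ and $F$ the gamma
CDF. A Monte Carlo path (`method = "mc"`) assigns each delivery a seeded
income draw conditional on its quintile band and counts exceedances; it
exists to mirror the simulation formulation and to validate the analytic
path (the suite checks agreement within three binomial standard errors).
The analytic path is the default because it is deterministic.

The incidence denominator is the pregnant-adolescent count implied by the
per-quintile percentages, $\sum_q (N/5)\,p_q$ — the convention that
reproduces the published incidences (0.4% India, 1.8% Niger); the per-age
denominator is available via `denominator = "age"`. Neither convention is
asserted to be the original authors' intent; both are exposed.

### The education counterfactual

`apply_policy()` reruns the whole pipeline with every pregnancy rate
multiplied by $1 - e$ and reports the difference. All three outcomes are
linear in the pregnancy rates, so undiscounted averted quantities equal
exactly $e$ times baseline — a property the tests assert to $10^{-9}$
relative, and the reason switching $e$ from 18% to 11% cuts every averted
outcome by exactly $1 - 11/18 \approx 39\%$. The programme cost is the
entering cohort ($N/5$) times the annual primary-education cost per pupil.

With `discount = TRUE`, outcomes accruing at ages 15–19 are discounted at
the configured rate (default 3%/year) over the five subsequent years with
factors $(1+r)^{-(a-15)}$: deaths averted are weighted by the per-age death
profile, cost and impoverishment outcomes by the per-age pregnancy profile,
and the education cost by uniform weights over the five years (the cost of
keeping a cohort in school is treated as spread over the same horizon as
the benefits). Discounting is off by default since all events fall within
five years.

### Estimating the education effect

`fit_education_effect()` regresses the adolescent pregnancy rate on mean
years of female education across countries (OLS) and converts the slope to
a relative reduction by scaling with the mean pregnancy rate — an
elasticity at the mean: $e = -\hat\beta / \bar y$. The scaling choice is
isolated in this one function. Its standard error uses the delta method
for the ratio, combining the slope's OLS standard error with the sampling
standard error of $\bar y$ (the two are uncorrelated under the linear
model). The simpler alternative — scaling the slope SE alone — ignores the
denominator's noise and measurably under-covers (about 93% instead of 95%
under the default simulation conditions below), which is why the
delta-method form is used.

The cross-country dataset behind the published 18% estimate is not
redistributable, so the fitted path is exercised on synthetic data with
known truth: `generate_education_dataset()` draws education years
uniformly on 3–9 (a realistic low/middle-income spread), sets the rate at
the midpoint to 15%, applies the generating slope
$\beta = -e \cdot \bar y$, and adds Gaussian noise with SD 0.04 — chosen
once so the cross-country $R^2$ lands in the moderate 0.4–0.7 regime
typical of such regressions. Rates are clipped to $[0,1]$; under the
defaults clipping is negligible, so recovery is unbiased. The calibration
experiment in the test suite runs 200 replicates from a single seeded
stream and checks that the 95% interval covers the generating effect at
its nominal rate (93–97% band). Passing these tests shows the estimator is
calibrated under the generator's linear-plus-noise world; it says nothing
about confounding or reverse causality in real cross-country data, which
the package deliberately does not model.

### Probabilistic sensitivity analysis

`run_psa()` varies the key parameters jointly: per trial it draws the MMR,
the age-specific relative risks, all OOP costs, the education cost per
pupil (gamma, moment-matched) and the education effect (logistic, scale
$\mathrm{sd}\cdot\sqrt{3}/\pi$), reruns the deterministic pipeline, and
reports 2.5/97.5 percentiles (linear interpolation between order
statistics, `quantile()` type 7) as 95% uncertainty ranges. Only the
education effect has a published SE (2%); every other SD defaults to 10%
of the point value and is overridable through `psa_spec()`. Because those
SDs are assumptions, the printed uncertainty ranges of the original study
are treated as bracketing checks, never as reproduction targets. GDP per
capita and the Gini index are held fixed by default (they are not in the
varied-parameter list); the income model is re-derived per trial only when
they appear in the spec list. Draws are inverse-CDF transforms of one
seeded uniform stream, which makes runs bit-reproducible per seed and
guarantees that enlarging every SD cannot narrow a range at a matched
seed. Beta moment matching fails loudly (naming the parameter) when the
requested SD is infeasible for the mean.

## Numerical choices and degenerate inputs

* Proportions are stored on the 0–1 scale; the config format requires an
  explicit `percent: true|false` flag so tabulated percentages cannot be
  silently misread by a factor of 100.
* A scalar quintile cost broadcasts to all five quintiles (Niger's
  transport cost is a single survey-wide $4).
* `pregnant_by_quintile` summing to zero while pregnancies exist is a
  degenerate-input error (shares undefined); all-zero `pregnant_by_age`
  simply yields zeros everywhere.
* A zero poverty line defines an empty poverty set, so the headcount is
  zero; the line has no packaged default and must be supplied explicitly.
* τ is restricted to (0, 1]; as τ → 0 every cost-incurring delivery
  becomes catastrophic, and the count is monotone non-increasing in τ.
* Quintile outcome vectors clamp values within numerical noise of zero to
  zero and refuse genuinely negative entries.

## Problem sizes

The default analyses are closed-form and run in milliseconds. Simulation
sizes used by the test suite — 10^6 draws for income-calibration checks,
2×10^5 for conditional-band checks, one draw per cost-incurring delivery
for Monte Carlo/analytic agreement, 200 replicates for effect-recovery
calibration, and a few hundred PSA trials (1000 is the analysis default) —
were chosen so the Monte Carlo standard errors are far below the
tolerances being asserted.

## Known limitations

* Table-level inputs are taken as given; the package does not parse survey
  microdata, convert currencies, or model within-country heterogeneity
  beyond quintiles.
* Average OOP costs per complicated delivery hide the cost gradient across
  complication severity (e.g. caesarean section).
* Lifetime economic consequences of adolescent pregnancy, morbidity and
  sequelae, and schooling-uptake dynamics are out of scope.
* The education–fertility relationship is associational; no causal
  machinery is attempted.
* Forgone care as impoverishment-avoidance behaviour is not modelled:
  women who never reach care appear in no impoverishment count.
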