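#' Per-quintile outcome vector
#'
#' Container for a result distributed across the five income quintiles
#' (poorest to richest): the per-quintile values, their total, and each
#' quintile's share of the total.
#'
#' @param values Numeric vector of length 5, non-negative, poorest first.
#' @param units Unit label (e.g. `"deaths"`, `"US$2014"`, `"cases"`).
#' @return Object of class `quintile_outcomes` with fields `values`, `total`,
#'   `shares`, `units`.
#' @export
quintile_outcomes <- function(values, units = "") {
  values <- as.numeric(values)
  if (length(values) != 5L || any(!is.finite(values))) {
    stop("values must be a finite numeric vector of length 5", call. = FALSE)
  }
  if (any(values < -1e-9 * max(abs(values), 1))) {
    stop("quintile values must be non-negative", call. = FALSE)
  }
  values <- pmax(values, 0)
  total <- sum(values)
  out <- list(values = values,
              total = total,
              shares = if (total > 0) values / total else rep(NA_real_, 5L),
              units = units)
  class(out) <- "quintile_outcomes"
  out
}

#' @export
print.quintile_outcomes <- function(x, digits = 4, ...) {
  cat(sprintf("<quintile_outcomes%s>\n",
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  m <- rbind(value = x$values, share = x$shares)
  colnames(m) <- paste0("Q", 1:5)
  print(signif(m, digits))
  cat(sprintf("  total: %s\n", format(signif(x$total, digits + 2))))
  invisible(x)
}

#' @export
as.data.frame.quintile_outcomes <- function(x, ...) {
  data.frame(quintile = paste0("Q", 1:5),
             value = x$values,
             share = x$shares,
             units = x$units,
             row.names = NULL)
}

#' Pregnancy, complication and care-seeking counts
#'
#' Reconciles the two pregnancy parameterizations into one ledger. The
#' per-age pregnancy percentages determine the absolute total: each single
#' year of age holds a fifth of the 15-19 population, so pregnancies at age
#' `a` are `(N/5) * pregnant_by_age[a]`. The per-quintile percentages are
#' used as *shares*: the total is split across quintiles in proportion to
#' `pregnant_by_quintile`. (The two vectors come from different survey
#' instruments and are not mutually consistent as absolute rates; see the
#' methods vignette.) Complicated deliveries are a fixed fraction of all
#' pregnancies, and only those with skilled birth attendance incur
#' out-of-pocket costs.
#'
#' @param params A [country_parameters()] object.
#' @param quintile_rule `"share"` (default; normalized per-quintile shares of
#'   the per-age total) or `"absolute"` (per-quintile percentages applied to
#'   `N/5` directly, for sensitivity exploration).
#' @return Object of class `pregnancy_ledger` with fields `per_age`
#'   (pregnancies at ages 15..19), `per_quintile`, `complicated_per_quintile`,
#'   `oop_incurring_per_quintile` (all counts), and `total`.
#' @export
#' @examples
#' build_pregnancy_ledger(load_country(ecea_fixture("niger")))$total
build_pregnancy_ledger <- function(params, quintile_rule = c("share", "absolute")) {
  stopifnot(inherits(params, "country_parameters"))
  quintile_rule <- match.arg(quintile_rule)
  cohort <- params$population_15_19 / 5
  per_age <- cohort * params$pregnant_by_age
  total <- sum(per_age)
  pq <- params$pregnant_by_quintile
  if (quintile_rule == "share") {
    if (sum(pq) <= 0 && total > 0) {
      stop("pregnant_by_quintile sums to zero: quintile shares are undefined",
           call. = FALSE)
    }
    shares <- if (sum(pq) > 0) pq / sum(pq) else rep(0, 5)
    per_quintile <- total * shares
  } else {
    per_quintile <- cohort * pq
  }
  complicated <- params$complicated_fraction * per_quintile
  ledger <- list(per_age = stats::setNames(per_age, 15:19),
                 per_quintile = stats::setNames(per_quintile, paste0("Q", 1:5)),
                 complicated_per_quintile =
                   stats::setNames(complicated, paste0("Q", 1:5)),
                 oop_incurring_per_quintile =
                   stats::setNames(complicated * params$usage_by_quintile,
                                   paste0("Q", 1:5)),
                 total = total,
                 quintile_rule = quintile_rule)
  class(ledger) <- "pregnancy_ledger"
  ledger
}

#' @export
print.pregnancy_ledger <- function(x, ...) {
  cat("<pregnancy_ledger>\n")
  cat("  per age (15-19):", format(round(x$per_age), big.mark = ","), "\n")
  cat("  per quintile:   ", format(round(x$per_quintile), big.mark = ","), "\n")
  cat("  total pregnancies:", format(round(x$total), big.mark = ","), "\n")
  invisible(x)
}

#' Adolescent maternal deaths per income quintile
#'
#' Deaths at age `a` are `pregnancies_a * rr_a * MMR / 100000`: the published
#' 15-49 maternal mortality ratio applies per pregnancy carried to term
#' (live-birth proxy) at the ages with relative risk 1, and is multiplied by
#' the age-specific relative risk where that risk is elevated (4.6 at age 15
#' by default). The age-summed total is then distributed across quintiles by
#' the normalized per-quintile pregnancy shares: mortality risk conditional
#' on pregnancy is taken as independent of income, so the equity
#' decomposition of deaths is exactly the pregnancy-share vector.
#'
#' @param params A [country_parameters()] object.
#' @return A [quintile_outcomes()] of deaths per year, with attributes
#'   `per_age` (deaths at ages 15..19) and `ledger`.
#' @export
#' @examples
#' maternal_deaths(load_country(ecea_fixture("india")))
maternal_deaths <- function(params) {
  ledger <- build_pregnancy_ledger(params)
  per_age <- ledger$per_age * params$rr_by_age * params$mmr / 1e5
  total <- sum(per_age)
  shares <- if (ledger$total > 0) ledger$per_quintile / ledger$total else rep(0.2, 5)
  out <- quintile_outcomes(total * shares, units = "deaths")
  attr(out, "per_age") <- per_age
  attr(out, "ledger") <- ledger
  out
}

#' Out-of-pocket expenditure per income quintile
#'
#' Total annual out-of-pocket spending on complicated adolescent deliveries:
#' for each quintile, the complicated deliveries that actually use care
#' (skilled birth attendance coverage `u_q`) each pay the quintile's direct
#' medical plus transport cost. Deliveries without care pay nothing (this is
#' the forgone-care group); maternal deaths do not reduce the cost base.
#'
#' @param params A [country_parameters()] object.
#' @return A [quintile_outcomes()] in US$2014, with attribute `ledger`.
#' @export
#' @examples
#' oop_costs(load_country(ecea_fixture("india")))$total  # about $17 million
oop_costs <- function(params) {
  ledger <- build_pregnancy_ledger(params)
  unit_cost <- params$oop_medical_by_quintile + params$oop_transport_by_quintile
  out <- quintile_outcomes(ledger$oop_incurring_per_quintile * unit_cost,
                           units = "US$2014")
  attr(out, "ledger") <- ledger
  out
}
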