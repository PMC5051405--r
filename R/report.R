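#' Bar chart of a per-quintile outcome
#'
#' Convenience figure mirroring the standard ECEA presentation: one bar per
#' income quintile, poorest to richest. Figures are a presentation layer
#' over the CSV outputs; all numeric results live in the CSVs.
#'
#' @param x A [quintile_outcomes()] object.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_quintiles <- function(x, title = "") {
  stopifnot(inherits(x, "quintile_outcomes"))
  d <- as.data.frame(x)
  d$quintile <- factor(d$quintile, levels = paste0("Q", 1:5))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quintile, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Income quintile (poorest to richest)",
                  y = x$units, title = title) +
    ggplot2::theme_minimal()
}

quintile_csv <- function(x, file) {
  d <- as.data.frame(x)
  d <- rbind(d, data.frame(quintile = "total", value = x$total,
                           share = if (x$total > 0) 1 else NA_real_,
                           units = x$units))
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Run the full analysis for one country configuration
#'
#' Orchestrates the whole pipeline for a country config file: maternal
#' deaths, out-of-pocket costs, catastrophic health expenditure (optionally
#' also the poverty headcount), the one-extra-year-of-education policy
#' impact, and optionally the probabilistic sensitivity analysis. Writes one
#' CSV per outcome, bar-chart figures, and a run manifest recording every
#' option, so a run can be reproduced bit for bit (analytic paths) or seed
#' for seed (Monte Carlo paths). The configuration is validated before any
#' output is written; an invalid config produces no partial outputs.
#'
#' @param config Path to a country YAML/JSON configuration.
#' @param outdir Output directory, created if needed.
#' @param seed Integer seed used for all stochastic paths (default 1).
#' @param threshold Catastrophic threshold override; defaults to the
#'   config's value.
#' @param effect Education effect override (proportion); defaults to the
#'   config's value.
#' @param discount Apply discounting to the policy impact (default FALSE).
#' @param poverty_line Optional poverty line; when given, the
#'   poverty-headcount variant is also written.
#' @param psa Run the probabilistic sensitivity analysis (default FALSE).
#' @param trials PSA trial count (default 1000).
#' @param plots Write figures.pdf (default TRUE).
#' @param verbose Log progress to stderr (default FALSE).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_full <- function(config, outdir, seed = 1, threshold = NULL,
                     effect = NULL, discount = FALSE, poverty_line = NULL,
                     psa = FALSE, trials = 1000, plots = TRUE,
                     verbose = FALSE) {
  say <- function(...) if (verbose) message("[eceamat] ", sprintf(...))

  params <- load_country(config)  # validates; failure precedes any output
  if (!is.null(threshold)) params$catastrophic_threshold <- threshold
  if (!is.null(effect)) params$education_effect <- effect
  if (!is.null(poverty_line)) params$poverty_line <- poverty_line
  validate_country_parameters(params)

  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- list()

  say("income model for %s", params$name)
  income <- build_income_model(params)

  say("maternal deaths")
  deaths <- maternal_deaths(params)
  paths$deaths <- quintile_csv(deaths, file.path(outdir, "deaths.csv"))

  say("out-of-pocket costs")
  oop <- oop_costs(params)
  paths$oop <- quintile_csv(oop, file.path(outdir, "oop.csv"))

  say("catastrophic expenditure (threshold %g%%)",
      100 * params$catastrophic_threshold)
  cat_res <- catastrophic_cases(params, income, method = "analytic",
                                seed = seed)
  paths$impoverishment <- quintile_csv(cat_res$cases_by_quintile,
                                       file.path(outdir, "impoverishment.csv"))

  if (!is.null(params$poverty_line)) {
    say("poverty headcount (line $%g)", params$poverty_line)
    ph <- poverty_headcount(params, income, seed = seed)
    paths$poverty_headcount <- quintile_csv(
      ph$cases_by_quintile, file.path(outdir, "poverty_headcount.csv"))
  }

  say("education policy impact")
  pol <- apply_policy(params, income, discount = discount)
  pol_df <- rbind(
    cbind(outcome = "deaths_averted", as.data.frame(pol$deaths_averted)),
    cbind(outcome = "oop_averted", as.data.frame(pol$oop_averted)),
    cbind(outcome = "catastrophic_averted",
          as.data.frame(pol$catastrophic_averted)),
    data.frame(outcome = "education_cost", quintile = "total",
               value = pol$education_cost, share = NA_real_, units = "US$2014"))
  paths$policy <- file.path(outdir, "policy.csv")
  utils::write.csv(pol_df, paths$policy, row.names = FALSE)

  if (psa) {
    say("probabilistic sensitivity analysis (%d trials)", trials)
    psa_res <- run_psa(params, n_trials = trials, seed = seed)
    paths$psa <- file.path(outdir, "psa.csv")
    utils::write.csv(psa_res$summary, paths$psa, row.names = FALSE)
  }

  if (plots) {
    say("figures")
    paths$figures <- file.path(outdir, "figures.pdf")
    grDevices::pdf(paths$figures, width = 7, height = 5)
    print(plot_quintiles(deaths, sprintf("%s: adolescent maternal deaths",
                                         params$name)))
    print(plot_quintiles(oop, sprintf("%s: out-of-pocket costs", params$name)))
    print(plot_quintiles(cat_res$cases_by_quintile,
                         sprintf("%s: catastrophic health expenditure",
                                 params$name)))
    print(plot_quintiles(pol$deaths_averted,
                         sprintf("%s: maternal deaths averted", params$name)))
    print(plot_quintiles(pol$catastrophic_averted,
                         sprintf("%s: catastrophic cases averted",
                                 params$name)))
    grDevices::dev.off()
  }

  manifest <- list(
    package = "eceamat",
    version = as.character(utils::packageVersion("eceamat")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = normalizePath(config),
    country = params$name,
    seed = seed,
    threshold = params$catastrophic_threshold,
    effect = params$education_effect,
    discount = discount,
    poverty_line = params$poverty_line,
    psa = psa,
    trials = if (psa) trials else NULL,
    outputs = vapply(paths, basename, character(1))
  )
  paths$manifest <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest[!vapply(manifest, is.null, logical(1))],
                   paths$manifest)

  say("done: %d files in %s", length(paths), outdir)
  invisible(paths)
}
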