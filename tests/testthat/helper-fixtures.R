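india_params <- function() load_country(ecea_fixture("india"))
niger_params <- function() load_country(ecea_fixture("niger"))

# 3-binomial-SE agreement bound for an analytic-vs-MC total, where the
# analytic per-quintile exceedance probabilities define the binomial variance
mc_3se <- function(result) {
  led <- attr(result, "ledger")
  n_q <- led$oop_incurring_per_quintile
  p_q <- ifelse(n_q > 0, result$cases_by_quintile$values / n_q, 0)
  3 * sqrt(sum(n_q * p_q * (1 - p_q)))
}
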