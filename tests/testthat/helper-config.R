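# Small complete-data generator configuration for fast deterministic tests:
# no full dropout, no attrition, no item missingness.
quick_config <- function(n = 150, seed = 1, ...) {
  generator_config(
    n_per_arm = c(sequential = n, simultaneous = n, control = n),
    seed = seed,
    dropout_logit_coeffs = c(intercept = -20, age = 0, lfs = 0),
    quarterly_dropout_hazard = 0,
    missing_item_prob = 0,
    ...
  )
}

# Participant-level analysis-set tibble built directly, for econ_eval tests
# that need controlled cost/effect distributions.
toy_arms <- function(n, mean_cost, mean_effect, sd_cost = 100,
                     sd_effect = 0.1, arms = c("a", "b", "c"), seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_along(arms), function(k) {
    tibble::tibble(
      id = paste0(arms[k], seq_len(n)),
      arm = arms[k],
      cost = stats::rnorm(n, mean_cost[k], sd_cost),
      effect = stats::rnorm(n, mean_effect[k], sd_effect)
    )
  }))
}
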