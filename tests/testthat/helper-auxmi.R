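# shared fixtures: all synthetic, generated at test time

small_config <- function(...) {
  defaults <- list(n = 200L, n_sim = 8L, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, args)
}

# one observed dataset under the given scenario, seeded
small_observed <- function(config = small_config(), seed = 1L) {
  set.seed(seed)
  d <- generate_complete(config)
  observe_dataset(d, impose_missing_outcome(d), impose_missing_aux(d))
}

# per-replicate paired estimates in wide format (one column per model)
wide_estimates <- function(result) {
  stats::reshape(as.data.frame(result)[c("replicate", "model", "estimate")],
                 idvar = "replicate", timevar = "model",
                 direction = "wide")
}

# bias/mcse for one model from a summarize_scenario() table
metric_of <- function(summary, model, field) {
  summary[[field]][summary$model == model]
}
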