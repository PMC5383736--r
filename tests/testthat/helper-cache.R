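# Shared fixtures, built once per test run. The full training set and the
# n = 50/condition experiment are expensive, so they are trained/run lazily
# and cached for every test file that needs them.

ag_cache <- new.env(parent = emptyenv())

# Small training set + sub-models for unit tests (2 actors x 10 moves).
small_models <- function() {
  if (is.null(ag_cache$small_models)) {
    cfg <- default_config()
    ts <- generate_training_set(2, 10, seed = 11, cfg = cfg)
    ag_cache$small_training <- ts
    ag_cache$small_models <- train_submodels(ts, cfg)
  }
  ag_cache$small_models
}

small_training <- function() {
  invisible(small_models())
  ag_cache$small_training
}

# Full-size models (6 x 50 per grip) as used by the experiment.
full_models <- function() {
  if (is.null(ag_cache$full_models)) {
    cfg <- default_config()
    ts <- generate_training_set(cfg$n_actors, cfg$n_moves_per_actor,
                                seed = activegaze:::derive_seed(7, "training"), cfg = cfg)
    ag_cache$full_models <- train_submodels(ts, cfg)
  }
  ag_cache$full_models
}

# The headline 2 x 2 experiment, 50 trials/condition.
acceptance_experiment <- function() {
  if (is.null(ag_cache$experiment)) {
    ag_cache$experiment <- run_experiment(50, seed_base = 7,
                                          models = full_models())
  }
  ag_cache$experiment
}

# Same experiment under the biased (.57, var .01) prior on BIG.
acceptance_experiment_biased <- function() {
  if (is.null(ag_cache$experiment_biased)) {
    cfg <- default_config()
    cfg$prior_mode <- "biased"
    ag_cache$experiment_biased <- run_experiment(50, seed_base = 7, cfg = cfg,
                                                 models = full_models())
  }
  ag_cache$experiment_biased
}

welch_p <- function(exp, a, b) {
  ct <- exp$contrasts
  ct$p_value[ct$contrast == paste(a, "vs", b)]
}

mean_arrival <- function(exp, cond) {
  s <- exp$summary
  s$mean_arrival_ms[s$condition == cond]
}

hand_fix_prop <- function(records) {
  vapply(records, function(r) {
    kinds <- vapply(r$events, `[[`, character(1), "target_kind")
    ep <- intersect(seq_along(kinds), 2:5)
    mean(kinds[ep] == "HAND")
  }, numeric(1))
}
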