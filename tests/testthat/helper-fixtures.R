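# Shared fixtures. Everything is generated in code; the heavyweight
# end-to-end experiments (used by two acceptance criteria) are computed
# once per test run and cached here.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# A short, cheap trial for unit tests: 2-s period, one cycle.
small_trial <- function(seed = 42L, period_s = 2, ...) {
  generate_trial(trial_config(period_s = period_s, seed = seed, ...))
}

small_window <- function() window_spec(200, 50, 1024)

# Held-out evaluation reports for periods x master seeds 1..5 (acceptance
# criteria on parameter recovery and period ordering share these).
acceptance_grid <- function() {
  cached("grid", {
    res <- list()
    for (T in c(2, 4, 8)) for (s in 1:5) {
      res[[sprintf("T%g_s%d", T, s)]] <-
        run_experiment(period_s = T, master_seed = s)$report
    }
    res
  })
}

# One small trained model shared by controller tests (20 trials keeps it
# fast; quality is irrelevant to the control-flow contracts under test).
small_model <- function() {
  cached("model", {
    ses <- generate_session(trial_config(period_s = 2, seed = 7),
                            n_trials = 20)
    sp <- split_data(make_dataset(ses, small_window()), 0.8, seed = 7)
    bpn_train(sp$train, train_spec(max_epochs = 500L, seed = 3))$model
  })
}
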