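# Shared small fixtures, built once per test run.

default_cfg <- make_center_out_config()
default_plant <- plant_params()
default_sys <- discretize_plant(default_plant)
default_grid <- duration_grid()

# a straight-line path from the center toward a target center
straight_path <- function(config, target, n_bins = 100, overshoot = 1) {
  ctr <- target_centers(config)[target, ]
  s <- seq(0, overshoot, length.out = n_bins)
  cbind(s * ctr[1], s * ctr[2])
}

# minimal hand-built trial: constant-rate spikes, pinned delay kinematics
toy_trial <- function(cued, n_neurons = 3, config = default_cfg,
                      p_spike = 0.05, mov_bins = 40) {
  eb <- ofcbmi:::epoch_bins(config)
  n_bins <- eb$instruct + mov_bins
  spikes <- matrix(rbinom(n_neurons * n_bins, 1, p_spike), n_neurons)
  kin <- matrix(0, n_bins, 6)
  kin[(eb$instruct + 1):n_bins, 1] <-
    seq(0, 0.1, length.out = mov_bins)
  trial_record(cued, spikes, kin, c(1L, eb$instruct))
}

# cached small simulated world shared by the heavier tests
sim_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- make_population(seed = 7)
      gain_cache <- build_gain_cache(default_cfg, default_grid, default_sys)
      train <- run_session(60, "manual", pop, default_cfg, default_sys,
                           default_grid, gain_cache = gain_cache, seed = 21)
      cache <<- list(
        pop = pop, gain_cache = gain_cache, train = train,
        target_model = fit_target_model(train$records, default_cfg),
        kin_fit = fit_kinematic_model(train$records)
      )
    }
    cache
  }
})
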