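#' Ground-truth synthetic neural population
#'
#' Draws a synthetic premotor population with known encoding: a fraction of
#' neurons carries target-tuned delay-period rates (baseline rates
#' log-normal around 5 spikes/s, multiplicatively modulated by a
#' cosine-of-preferred-target profile), and a fraction carries log-linear
#' peri-movement kinematic tuning with random preferred directions.  The
#' default sizes mirror typical multielectrode premotor recordings: 20
#' neurons, about 48% target-tuned and 47% kinematically tuned, the latter
#' split 57/15/28% into position-only, velocity-only and both.
#'
#' Tuning magnitudes are scaled to the default workspace (reach distance
#' 0.1, speeds around 0.25 units/s): position gradients give roughly a
#' factor-e rate swing across the reach and velocity gradients somewhat
#' less, which puts ensemble delay decoding near the 80% regime typical of
#' ~20-neuron premotor ensembles.
#'
#' @param n_neurons Number of neurons.
#' @param n_targets Number of targets.
#' @param fraction_target_tuned Fraction with target-dependent delay rates.
#' @param fraction_kinematic_tuned Fraction with kinematic tuning.
#' @param baseline_rate Median baseline rate, spikes/s.
#' @param baseline_sdlog Log-scale spread of baseline rates.
#' @param target_modulation Mean log-rate modulation depth of target tuning.
#' @param beta_p_scale Mean magnitude of position log-gradients, 1/unit.
#' @param beta_v_scale Mean magnitude of velocity log-gradients, s/unit.
#' @param category_probs Probabilities of `position_only`, `velocity_only`,
#'   `both` among kinematically tuned neurons.
#' @param bin_s Bin width, s.
#' @param seed Integer seed (populations are reproducible given the seed).
#' @return Object of class `bmi_population`: `target_rates` (neurons x
#'   targets, spikes/s), `kin_model` (`bmi_kinematic_model` of the ground
#'   truth), `target_tuned` / `kin_tuned` logical vectors, `category` per
#'   neuron.
#' @export
make_population <- function(n_neurons = 20L, n_targets = 4L,
                            fraction_target_tuned = 0.48,
                            fraction_kinematic_tuned = 0.47,
                            baseline_rate = 5, baseline_sdlog = 0.5,
                            target_modulation = 0.4,
                            beta_p_scale = 8, beta_v_scale = 2.5,
                            category_probs = c(position_only = 0.57,
                                               velocity_only = 0.15,
                                               both = 0.28),
                            bin_s = 0.005, seed = 1) {
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 1L) stop("need at least one neuron", call. = FALSE)
  if (fraction_target_tuned < 0 || fraction_target_tuned > 1 ||
      fraction_kinematic_tuned < 0 || fraction_kinematic_tuned > 1)
    stop("tuned fractions must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  baseline <- stats::rlnorm(n_neurons, log(baseline_rate), baseline_sdlog)
  angles <- 2 * pi * (seq_len(n_targets) - 1L) / n_targets

  n_tt <- round(fraction_target_tuned * n_neurons)
  target_tuned <- rep(FALSE, n_neurons)
  target_tuned[sample.int(n_neurons, n_tt)] <- TRUE
  target_rates <- matrix(baseline, n_neurons, n_targets)
  for (i in which(target_tuned)) {
    kappa <- abs(stats::rnorm(1, target_modulation, target_modulation / 2))
    pref <- stats::runif(1, 0, 2 * pi)
    target_rates[i, ] <- baseline[i] * exp(kappa * cos(angles - pref))
  }

  n_kt <- round(fraction_kinematic_tuned * n_neurons)
  kin_tuned <- rep(FALSE, n_neurons)
  kin_tuned[sample.int(n_neurons, n_kt)] <- TRUE
  beta <- matrix(0, n_neurons, 4,
                 dimnames = list(NULL, c("p_x", "p_y", "v_x", "v_y")))
  category <- rep("untuned", n_neurons)
  cats <- names(category_probs)
  for (i in which(kin_tuned)) {
    cat_i <- sample(cats, 1, prob = category_probs)
    category[i] <- cat_i
    if (cat_i %in% c("position_only", "both")) {
      mag <- abs(stats::rnorm(1, beta_p_scale, beta_p_scale / 4))
      th <- stats::runif(1, 0, 2 * pi)
      beta[i, 1:2] <- mag * c(cos(th), sin(th))
    }
    if (cat_i %in% c("velocity_only", "both")) {
      mag <- abs(stats::rnorm(1, beta_v_scale, beta_v_scale / 4))
      th <- stats::runif(1, 0, 2 * pi)
      beta[i, 3:4] <- mag * c(cos(th), sin(th))
    }
  }
  structure(list(
    target_rates = target_rates,
    kin_model = kinematic_model(log(baseline), beta, bin_s),
    target_tuned = target_tuned, kin_tuned = kin_tuned,
    category = category, baseline = baseline, n_targets = n_targets
  ), class = "bmi_population")
}

# one bin of Bernoulli spiking at per-neuron rates (spikes/s)
draw_spikes <- function(rates, bin_s) {
  p <- pmin(rates * bin_s, 0.95)
  as.integer(stats::runif(length(p)) < p)
}

# delay-period spiking for a cued target over n_bins
simulate_delay_spikes <- function(pop, cued, n_bins, bin_s) {
  p <- pmin(pop$target_rates[, cued] * bin_s, 0.95)
  matrix(stats::rbinom(length(p) * n_bins, 1L, rep(p, n_bins)),
         nrow = length(p))
}

#' Precompute LQG gain schedules for every (target, duration) pair
#'
#' @param config A `bmi_task_config`.
#' @param grid A `bmi_duration_grid`.
#' @param sys A `bmi_lti`.
#' @param cost_weights Optional cost-weight overrides (`w_v`, `w_f`, `r`).
#' @return Nested list: `[[target]][[duration index]]` of `bmi_gains`.
#' @export
build_gain_cache <- function(config, grid, sys, cost_weights = NULL) {
  centers <- target_centers(config)
  cw <- as.list(cost_weights %||% list())
  lapply(seq_len(config$n_targets), function(m) {
    lapply(grid$bins, function(Tb) {
      args <- c(list(target = centers[m, ], T_bins = Tb), cw)
      solve_lqg(sys, do.call(cost_spec, args))
    })
  })
}

#' Simulate one manual-control (training) trial
#'
#' The cued target is drawn uniformly; the subject's intended movement
#' duration is drawn uniformly from the duration grid.  The reach is a
#' noisy LQG feedback rollout that continues with the terminal gain frozen
#' until it enters a target disk or times out.  Delay-period spikes are
#' drawn from the target rates over the full instruction epoch (the cursor
#' is pinned at the center); movement spikes are drawn per 5 ms bin from
#' the log-linear kinematic model along the realized states.
#'
#' @param pop A `bmi_population`.
#' @param config A `bmi_task_config`.
#' @param sys A `bmi_lti` (the subject's plant).
#' @param gain_cache From [build_gain_cache()].
#' @param grid A `bmi_duration_grid`.
#' @return A `bmi_trial_record` with its scored outcome.
#' @export
simulate_manual_trial <- function(pop, config, sys, gain_cache, grid) {
  eb <- epoch_bins(config)
  bin_s <- config$bin_ms / 1000
  cued <- sample.int(config$n_targets, 1L)
  dur_i <- sample.int(length(grid$bins), 1L)
  gains <- gain_cache[[cued]][[dur_i]]
  delay_spikes <- simulate_delay_spikes(pop, cued, eb$instruct, bin_s)
  sd_f <- sqrt(diag(sys$W)[5:6])
  x <- numeric(6)
  kin <- matrix(0, eb$timeout, 6)
  mov_spikes <- matrix(0L, length(pop$baseline), eb$timeout)
  n_mov <- eb$timeout
  r2 <- config$target_radius^2
  centers <- target_centers(config)
  for (t in seq_len(eb$timeout)) {
    u <- -gain_at(gains, t) %*% (x - gains$x_star)
    x <- drop(sys$A %*% x + sys$B %*% u)
    x[5:6] <- x[5:6] + stats::rnorm(2, 0, sd_f)
    kin[t, ] <- x
    mov_spikes[, t] <- draw_spikes(
      rate_at(pop$kin_model, seq_along(pop$baseline), x), bin_s)
    d2 <- (centers[, 1] - x[1])^2 + (centers[, 2] - x[2])^2
    if (any(d2 <= r2)) { n_mov <- t; break }
  }
  kin <- kin[seq_len(n_mov), , drop = FALSE]
  mov_spikes <- mov_spikes[, seq_len(n_mov), drop = FALSE]
  spikes <- cbind(delay_spikes, mov_spikes)
  kinematics <- rbind(matrix(0, eb$instruct, 6), kin)
  outcome <- score_trial(kin[, 1:2, drop = FALSE], config, cued)
  trial_record(cued, spikes, kinematics, c(1L, eb$instruct), outcome)
}

#' Simulate one closed-loop BMI trial
#'
#' During the delay the subject emits target-tuned spikes and the decoder's
#' `on_delay` consumes the decoding window while the cursor stays pinned at
#' the center.  During movement, each 5 ms bin: the subject reads the
#' displayed (decoded) cursor position — perfect visual feedback — slaves
#' the position components of its internal state to it while keeping its
#' own intended velocity and force, issues its LQG control toward the cued
#' target, advances its internal state, and emits spikes from the kinematic
#' model at that internal state.  The decoder consumes the spikes and moves
#' the cursor.  The trial ends at disk entry or time-out and is scored on
#' the cursor path.
#'
#' @param pop A `bmi_population`.
#' @param decoder A decoder interface (see [make_two_stage_decoder()] and
#'   friends): list with functions `on_delay(delay_spikes, cued)` and
#'   `step(dN)` returning the new cursor position.
#' @param config A `bmi_task_config`.
#' @param sys A `bmi_lti` (the subject's internal plant).
#' @param gain_cache From [build_gain_cache()] (the subject's internal
#'   gains).
#' @param grid A `bmi_duration_grid`.
#' @return A `bmi_trial_record`; `kinematics` holds the cursor (decoded)
#'   position with finite-difference velocity.  Decoder errors abort the
#'   trial (cause `timeout`, attribute `decoder_error`).
#' @export
simulate_closed_loop_trial <- function(pop, decoder, config, sys, gain_cache,
                                       grid) {
  eb <- epoch_bins(config)
  bin_s <- config$bin_ms / 1000
  cued <- sample.int(config$n_targets, 1L)
  dur_i <- sample.int(length(grid$bins), 1L)
  gains <- gain_cache[[cued]][[dur_i]]
  delay_spikes <- simulate_delay_spikes(pop, cued, eb$instruct, bin_s)
  decode_idx <- (eb$instruct - eb$decode + 1L):eb$instruct
  ok <- TRUE
  tryCatch(decoder$on_delay(delay_spikes[, decode_idx, drop = FALSE], cued),
           error = function(e) ok <<- FALSE)
  sd_f <- sqrt(diag(sys$W)[5:6])
  x <- numeric(6)                       # subject's internal state
  cursor <- c(0, 0)
  kin <- matrix(0, eb$timeout, 6)
  mov_spikes <- matrix(0L, length(pop$baseline), eb$timeout)
  n_mov <- eb$timeout
  r2 <- config$target_radius^2
  centers <- target_centers(config)
  if (ok) {
    for (t in seq_len(eb$timeout)) {
      s <- x
      s[1:2] <- cursor                  # perfect feedback of the display
      u <- -gain_at(gains, t) %*% (s - gains$x_star)
      x <- drop(sys$A %*% s + sys$B %*% u)
      x[5:6] <- x[5:6] + stats::rnorm(2, 0, sd_f)
      dN <- draw_spikes(rate_at(pop$kin_model, seq_along(pop$baseline), x),
                        bin_s)
      mov_spikes[, t] <- dN
      new_cursor <- tryCatch(decoder$step(dN), error = function(e) NULL)
      if (is.null(new_cursor)) { ok <- FALSE; n_mov <- t; break }
      cursor <- as.numeric(new_cursor)[1:2]
      kin[t, 1:2] <- cursor
      if (t > 1L) kin[t, 3:4] <- (cursor - kin[t - 1L, 1:2]) / bin_s
      d2 <- (centers[, 1] - cursor[1])^2 + (centers[, 2] - cursor[2])^2
      if (any(d2 <= r2)) { n_mov <- t; break }
    }
  } else n_mov <- 1L
  kin <- kin[seq_len(n_mov), , drop = FALSE]
  mov_spikes <- mov_spikes[, seq_len(n_mov), drop = FALSE]
  spikes <- cbind(delay_spikes, mov_spikes)
  kinematics <- rbind(matrix(0, eb$instruct, 6), kin)
  outcome <- score_trial(kin[, 1:2, drop = FALSE], config, cued)
  rec <- trial_record(cued, spikes, kinematics, c(1L, eb$instruct), outcome)
  if (!ok) attr(rec, "decoder_error") <- TRUE
  rec
}

#' Run a simulated session
#'
#' Simulates a seeded sequence of manual-control or closed-loop trials.  A
#' single session seed drives everything; per-trial RNG streams are derived
#' from it by counter so that sessions are reproducible trial by trial.
#'
#' @param n_trials Number of trials (default 89, a typical daily training
#'   session).
#' @param mode `"manual"` or `"closed_loop"`.
#' @param pop A `bmi_population`.
#' @param config A `bmi_task_config`.
#' @param sys A `bmi_lti`.
#' @param grid A `bmi_duration_grid`.
#' @param decoder Decoder interface (closed-loop mode only).  If the
#'   decoder has a `reset()` element it is called before each trial.
#' @param gain_cache Optional precomputed [build_gain_cache()] output.
#' @param seed Integer session seed.
#' @return Object of class `bmi_session`: list with `records`, `summary`
#'   (from [summarize_session()]), `mode` and `seed`.
#' @export
run_session <- function(n_trials = 89L, mode = c("manual", "closed_loop"),
                        pop, config, sys, grid, decoder = NULL,
                        gain_cache = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "closed_loop" && is.null(decoder))
    stop("closed-loop mode needs a decoder", call. = FALSE)
  if (is.null(gain_cache)) gain_cache <- build_gain_cache(config, grid, sys)
  records <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    set.seed((as.integer(seed) %% 100000L) * 20011L + i)
    if (!is.null(decoder$reset)) decoder$reset()
    records[[i]] <- if (mode == "manual")
      simulate_manual_trial(pop, config, sys, gain_cache, grid)
    else
      simulate_closed_loop_trial(pop, decoder, config, sys, gain_cache, grid)
  }
  structure(list(records = records, summary = summarize_session(records),
                 mode = mode, seed = seed),
            class = "bmi_session")
}
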