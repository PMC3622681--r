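# Closed-loop decoder interfaces.  Every factory returns a list of closures
# with the per-bin contract used by simulate_closed_loop_trial():
#   on_delay(delay_spikes, cued)  consume the delay decoding window
#   step(dN)                      consume one bin of spikes, return the
#                                 cursor position (length 2)
#   reset()                       clear state before a new trial
# Honest decoders ignore the `cued` argument; it exists for the oracle
# reference decoder.

#' Two-stage closed-loop decoder (target ML + FC-P-PPF)
#'
#' Stage one decodes the target by maximum likelihood from the delay window;
#' stage two runs the duration-mixture feedback-controlled point process
#' filter toward the decoded target.
#'
#' @param target_model A `bmi_target_rate_model`.
#' @param kin_model A `bmi_kinematic_model`.
#' @param config A `bmi_task_config`.
#' @param sys A `bmi_lti` (the decoder's prior plant).
#' @param grid A `bmi_duration_grid`.
#' @param cost_weights Optional cost-weight overrides.
#' @return Decoder interface list; also exposes `decoded_target()`.
#' @export
make_two_stage_decoder <- function(target_model, kin_model, config, sys,
                                   grid, cost_weights = NULL) {
  bin_s <- config$bin_ms / 1000
  centers <- target_centers(config)
  bank <- NULL
  target <- NA_integer_
  list(
    on_delay = function(delay_spikes, cued = NULL) {
      target <<- decode_target_ml(delay_spikes, target_model, bin_s)$predicted
      bank <<- filter_bank(centers[target, ], grid, sys, cost_weights)
      invisible(target)
    },
    step = function(dN) {
      bank <<- filter_bank_step(bank, dN, sys, kin_model, bin_s)
      bank$estimate[1:2]
    },
    reset = function() { bank <<- NULL; target <<- NA_integer_ },
    decoded_target = function() target
  )
}

#' Random-walk PPF closed-loop decoder
#'
#' The second-stage ablation: no target information, smoothness-only
#' random-walk prior (`B = 0`).
#'
#' @param kin_model A `bmi_kinematic_model`.
#' @param sys A `bmi_lti`.
#' @return Decoder interface list.
#' @export
make_rw_ppf_decoder <- function(kin_model, sys) {
  belief <- gaussian_belief()
  list(
    on_delay = function(delay_spikes, cued = NULL) invisible(NULL),
    step = function(dN) {
      pred <- ppf_predict(belief, sys, NULL)
      belief <<- ppf_update(pred, dN, kin_model)
      belief$mean[1:2]
    },
    reset = function() belief <<- gaussian_belief()
  )
}

#' Stage-1-only closed-loop decoder
#'
#' Decodes the target from the delay window, then ignores the movement
#' spikes and replays the noiseless feedback-controlled prior rollout to
#' the decoded target: its acquisition accuracy equals the stage-1 target
#' classification accuracy.
#'
#' @param target_model A `bmi_target_rate_model`.
#' @param config A `bmi_task_config`.
#' @param sys A `bmi_lti`.
#' @param T_bins Assumed movement horizon in bins (default 120, i.e. 0.6 s).
#' @param cost_weights Optional cost-weight overrides.
#' @return Decoder interface list; also exposes `decoded_target()`.
#' @export
make_stage1_decoder <- function(target_model, config, sys, T_bins = 120L,
                                cost_weights = NULL) {
  bin_s <- config$bin_ms / 1000
  centers <- target_centers(config)
  cw <- as.list(cost_weights %||% list())
  target <- NA_integer_
  x <- numeric(6)
  gains <- NULL
  t <- 0L
  list(
    on_delay = function(delay_spikes, cued = NULL) {
      target <<- decode_target_ml(delay_spikes, target_model, bin_s)$predicted
      args <- c(list(target = centers[target, ], T_bins = T_bins), cw)
      gains <<- solve_lqg(sys, do.call(cost_spec, args))
      invisible(target)
    },
    step = function(dN) {
      t <<- t + 1L
      u <- -gain_at(gains, t) %*% (x - gains$x_star)
      x <<- drop(sys$A %*% x + sys$B %*% u)
      x[1:2]
    },
    reset = function() { target <<- NA_integer_; x <<- numeric(6)
      gains <<- NULL; t <<- 0L },
    decoded_target = function() target
  )
}

#' Oracle and frozen reference decoders
#'
#' The oracle decoder is told the cued target and replays the noiseless
#' prior rollout to it (an upper reference: geometry sanity).  The frozen
#' decoder never moves the cursor (a lower reference: guaranteed timeout).
#'
#' @param config A `bmi_task_config`.
#' @param sys A `bmi_lti`.
#' @param T_bins Assumed movement horizon in bins.
#' @param cost_weights Optional cost-weight overrides.
#' @return Decoder interface list.
#' @export
make_oracle_decoder <- function(config, sys, T_bins = 120L,
                                cost_weights = NULL) {
  centers <- target_centers(config)
  cw <- as.list(cost_weights %||% list())
  x <- numeric(6)
  gains <- NULL
  t <- 0L
  list(
    on_delay = function(delay_spikes, cued = NULL) {
      if (is.null(cued)) stop("oracle decoder needs the cued target")
      args <- c(list(target = centers[cued, ], T_bins = T_bins), cw)
      gains <<- solve_lqg(sys, do.call(cost_spec, args))
      invisible(cued)
    },
    step = function(dN) {
      t <<- t + 1L
      u <- -gain_at(gains, t) %*% (x - gains$x_star)
      x <<- drop(sys$A %*% x + sys$B %*% u)
      x[1:2]
    },
    reset = function() { x <<- numeric(6); gains <<- NULL; t <<- 0L }
  )
}

#' @rdname make_oracle_decoder
#' @export
make_frozen_decoder <- function() {
  list(
    on_delay = function(delay_spikes, cued = NULL) invisible(NULL),
    step = function(dN) c(0, 0),
    reset = function() invisible(NULL)
  )
}

#' Closed-loop adapter for a fitted ridge decoder
#'
#' Maintains the trailing 100 ms spike window and the lagged standardized
#' rate history so a [select_ridge_model()] fit can drive the cursor one
#' 5 ms bin at a time.
#'
#' @param decoder A `bmi_ridge_decoder`.
#' @param n_neurons Neuron count.
#' @param window_ms Rate window, ms.
#' @param step_ms Bin step, ms.
#' @return Decoder interface list.
#' @export
make_ridge_closed_loop_decoder <- function(decoder, n_neurons,
                                           window_ms = 100, step_ms = 5) {
  w <- as.integer(round(window_ms / step_ms))
  spike_buf <- matrix(0L, n_neurons, 0)
  lag_buf <- matrix(0, decoder$K, n_neurons)   # newest first
  t <- 0L
  list(
    on_delay = function(delay_spikes, cued = NULL) invisible(NULL),
    step = function(dN) {
      t <<- t + 1L
      spike_buf <<- cbind(spike_buf, as.integer(dN))
      if (ncol(spike_buf) > w) spike_buf <<- spike_buf[, -1, drop = FALSE]
      eff_s <- ncol(spike_buf) * step_ms / 1000
      rate <- rowSums(spike_buf) / eff_s
      z <- (rate - decoder$mu) / decoder$sd
      lag_buf <<- rbind(z, lag_buf[-decoder$K, , drop = FALSE])
      zlags <- as.numeric(t(lag_buf))
      if (t < decoder$K) zlags[(t * n_neurons + 1L):length(zlags)] <- 0
      drop(crossprod(decoder$fit$coefficients, zlags)) + decoder$fit$q_mean
    },
    reset = function() {
      spike_buf <<- matrix(0L, n_neurons, 0)
      lag_buf <<- matrix(0, decoder$K, n_neurons)
      t <<- 0L
    }
  )
}
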