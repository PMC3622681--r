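#' Delay-period ensemble log-likelihood per target
#'
#' Computes, for every candidate target, the log-likelihood of the binary
#' delay-window spiking of the ensemble under the homogeneous-Poisson target
#' rate model, treating neurons as conditionally independent given the
#' target.  Each 5 ms bin contributes the exact Bernoulli term
#' `dN log(lambda Delta) + (1 - dN) log(1 - lambda Delta)` with
#' `lambda Delta` the per-bin event probability (clamped below 1).
#'
#' Because rates are constant over the window, the log-likelihood depends on
#' the spikes only through per-neuron counts, which is how it is computed.
#'
#' @param spikes Integer matrix, neurons x delay-window bins, of binary
#'   spike indicators.
#' @param model A `bmi_target_rate_model` covering the same neurons.
#' @param bin_s Bin width, s.
#' @return Numeric vector of per-target log-likelihoods.
#' @export
ensemble_delay_loglik <- function(spikes, model, bin_s = 0.005) {
  spikes <- as.matrix(spikes)
  if (nrow(spikes) != nrow(model$rates))
    stop("spike matrix and rate model disagree on the neuron count",
         call. = FALSE)
  K <- ncol(spikes)
  n_c <- rowSums(spikes)
  p <- pmin(model$rates * bin_s, 0.999999)   # neurons x targets
  colSums(n_c * log(p) + (K - n_c) * log1p(-p))
}

#' Maximum-likelihood target decoding from delay activity
#'
#' Predicts the intended target as the argmax of the per-target ensemble
#' log-likelihoods.  Exact ties are broken uniformly at random using the
#' current RNG state, so a fixed seed reproduces the tie-break.
#'
#' @inheritParams ensemble_delay_loglik
#' @return An object of class `bmi_target_posterior`: list with `loglik`
#'   (per target), `predicted` (target id) and `margin` (log-likelihood gap
#'   between the best and runner-up targets).
#' @export
decode_target_ml <- function(spikes, model, bin_s = 0.005) {
  ll <- ensemble_delay_loglik(spikes, model, bin_s)
  best <- which(ll >= max(ll) - 1e-12)
  predicted <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
  s <- sort(ll, decreasing = TRUE)
  structure(list(loglik = ll, predicted = as.integer(predicted),
                 margin = if (length(s) > 1L) s[1] - s[2] else Inf),
            class = "bmi_target_posterior")
}

# leave-one-out target decoding over a session; returns predicted ids.
# neurons: optional subset of neurons to use.
loo_target_predictions <- function(records, config, rate_floor = 0.1,
                                   neurons = NULL) {
  bin_s <- config$bin_ms / 1000
  n_neurons <- nrow(records[[1]]$spikes)
  if (is.null(neurons)) neurons <- seq_len(n_neurons)
  # raw counts and exposures let single trials be subtracted in O(1)
  counts <- matrix(0, n_neurons, config$n_targets)
  exposure <- numeric(config$n_targets)
  wins <- lapply(records, delay_window_spikes, config = config)
  for (i in seq_along(records)) {
    tg <- records[[i]]$cued_target
    counts[, tg] <- counts[, tg] + rowSums(wins[[i]])
    exposure[tg] <- exposure[tg] + ncol(wins[[i]]) * bin_s
  }
  vapply(seq_along(records), function(i) {
    tg <- records[[i]]$cued_target
    cnt <- counts
    exp_i <- exposure
    cnt[, tg] <- cnt[, tg] - rowSums(wins[[i]])
    exp_i[tg] <- exp_i[tg] - ncol(wins[[i]]) * bin_s
    if (exp_i[tg] <= 0)
      stop("leave-one-out needs >= 2 trials per target", call. = FALSE)
    rates <- pmax(sweep(cnt, 2, exp_i, "/"), rate_floor)
    m <- structure(list(rates = rates[neurons, , drop = FALSE],
                        exposure_s = exp_i, rate_floor = rate_floor),
                   class = "bmi_target_rate_model")
    decode_target_ml(wins[[i]][neurons, , drop = FALSE], m, bin_s)$predicted
  }, 0L)
}

#' Leave-one-out target prediction accuracy
#'
#' Cross-validated (leave-one-trial-out) accuracy of the maximum-likelihood
#' target decoder on a session, optionally restricted to a neuron subset.
#'
#' @param records List of `bmi_trial_record`s (>= 2 trials per target).
#' @param config A `bmi_task_config`.
#' @param neurons Optional neuron indices to use (default: all).
#' @param rate_floor Minimum fitted rate, spikes/s.
#' @return Fraction of trials with the cued target predicted, in `[0, 1]`.
#' @export
target_accuracy_loo <- function(records, config, neurons = NULL,
                                rate_floor = 0.1) {
  pred <- loo_target_predictions(records, config, rate_floor, neurons)
  cued <- vapply(records, function(r) r$cued_target, 0L)
  mean(pred == cued)
}

#' Neuron-dropping analysis of target prediction
#'
#' Ranks neurons by their single-neuron leave-one-out target decoding
#' accuracy, then reports the cumulative accuracy of the top-k ensembles for
#' k = 1..`k_max`, together with the smallest k whose accuracy reaches 90%
#' of the full-ensemble accuracy.
#'
#' @param records List of `bmi_trial_record`s.
#' @param config A `bmi_task_config`.
#' @param k_max Largest ensemble size to evaluate (truncated, with a
#'   warning, to the neuron count).
#' @param rate_floor Minimum fitted rate, spikes/s.
#' @return List with `single_accuracy` (per neuron), `order` (ranked neuron
#'   ids), `ensemble_accuracy` (length `k_max`), `full_accuracy`, and
#'   `k_90` (smallest k with accuracy >= 0.9 * `full_accuracy`).
#' @export
neuron_dropping_curve <- function(records, config, k_max = NULL,
                                  rate_floor = 0.1) {
  n_neurons <- nrow(records[[1]]$spikes)
  if (is.null(k_max)) k_max <- n_neurons
  if (k_max > n_neurons) {
    warning("k_max exceeds the neuron count; truncating")
    k_max <- n_neurons
  }
  single <- vapply(seq_len(n_neurons), function(c_i)
    target_accuracy_loo(records, config, neurons = c_i,
                        rate_floor = rate_floor), 0)
  ord <- order(single, decreasing = TRUE)
  acc <- vapply(seq_len(k_max), function(k)
    target_accuracy_loo(records, config, neurons = ord[seq_len(k)],
                        rate_floor = rate_floor), 0)
  full <- target_accuracy_loo(records, config, rate_floor = rate_floor)
  k_90 <- which(acc >= 0.9 * full)
  list(single_accuracy = single, order = ord, ensemble_accuracy = acc,
       full_accuracy = full,
       k_90 = if (length(k_90)) min(k_90) else NA_integer_)
}
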