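#' Gaussian belief over the kinematic state
#'
#' @param mean Numeric 6-vector.
#' @param cov 6x6 covariance matrix; symmetrized and eigenvalue-clipped at
#'   construction.
#' @return An object of class `bmi_belief`.
#' @export
gaussian_belief <- function(mean = numeric(6), cov = diag(1e-6, 6)) {
  mean <- as.numeric(mean)
  if (length(mean) != 6L) stop("belief mean must be a 6-vector", call. = FALSE)
  structure(list(mean = mean, cov = make_psd(cov)), class = "bmi_belief")
}

# symmetrize and clip tiny negative eigenvalues (tolerance -1e-10)
make_psd <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-10 || any(e$values < 0)) {
    v <- pmax(e$values, 0)
    S <- e$vectors %*% (v * t(e$vectors))
    S <- (S + t(S)) / 2
  }
  S
}

log_det_pd <- function(S) 2 * sum(log(diag(chol(S))))

#' Point process filter prediction step
#'
#' Moves a Gaussian belief one bin forward through the feedback-controlled
#' prior: the mean follows `A m + B u` with `u = -L_t (m - x*)` (the control
#' the subject would issue from the fed-back cursor state, proxied by the
#' posterior mean), and the covariance propagates through the closed loop,
#' `(A - B L_t) Cov (A - B L_t)' + W`.  An open-loop covariance variant
#' (`A Cov A' + W`) is available for sensitivity checks.
#'
#' @param belief A `bmi_belief` (previous posterior).
#' @param sys A `bmi_lti`.
#' @param L_t 2x6 feedback gain for this step (use `NULL` for the
#'   random-walk prior: no control term).
#' @param x_star Augmented goal state (6-vector); ignored when `L_t` is
#'   `NULL`.
#' @param closed_loop_cov Propagate the covariance through `A - B L_t`
#'   (default) instead of `A`.
#' @return A `bmi_belief` (one-step prediction).
#' @export
ppf_predict <- function(belief, sys, L_t, x_star = numeric(6),
                        closed_loop_cov = TRUE) {
  stopifnot(inherits(belief, "bmi_belief"))
  m <- belief$mean
  if (is.null(L_t)) {
    mean_new <- drop(sys$A %*% m)
    Acl <- sys$A
  } else {
    if (!all(dim(L_t) == c(2L, 6L)))
      stop("gain L_t must be 2 x 6", call. = FALSE)
    u <- -L_t %*% (m - x_star)
    mean_new <- drop(sys$A %*% m + sys$B %*% u)
    Acl <- if (closed_loop_cov) sys$A - sys$B %*% L_t else sys$A
  }
  cov_new <- Acl %*% belief$cov %*% t(Acl) + sys$W
  gaussian_belief(mean_new, cov_new)
}

# embed per-neuron kinematic tuning vectors into state space (force rows 0)
beta_tilde <- function(model) {
  rbind(t(model$beta), matrix(0, 2, nrow(model$beta)))   # 6 x neurons
}

#' Point process filter update step
#'
#' Folds one bin of binary ensemble spiking into the predicted belief using
#' the Gaussian (Laplace) approximation of the point-process posterior, in
#' information form: with per-neuron intensities `lambda_c` evaluated at the
#' predicted mean and tuning vectors `b_c` embedded in state space,
#' `Cov_post^{-1} = Cov_pred^{-1} + sum_c lambda_c Delta b_c b_c'` and
#' `mean_post = mean_pred + Cov_post sum_c b_c (dN_c - lambda_c Delta)`.
#' The correction is the innovation "spike indicator minus predicted spike
#' probability"; with no neurons the posterior equals the prediction.
#'
#' @param pred A `bmi_belief` (one-step prediction).
#' @param dN Integer vector of per-neuron spike indicators for this bin.
#' @param model A `bmi_kinematic_model`.
#' @param bin_s Bin width, s.
#' @return A `bmi_belief` (posterior).
#' @export
ppf_update <- function(pred, dN, model, bin_s = model$bin_s) {
  stopifnot(inherits(pred, "bmi_belief"))
  n_neurons <- length(model$alpha)
  if (length(dN) != n_neurons)
    stop("dN length must match the neuron count", call. = FALSE)
  if (n_neurons == 0L) return(pred)
  lam <- rate_at(model, seq_len(n_neurons), pred$mean)
  p_spike <- lam * bin_s
  Bt <- beta_tilde(model)                       # 6 x C
  info_prior <- chol2inv_safe(pred$cov)
  info_post <- info_prior + Bt %*% (p_spike * t(Bt))
  cov_post <- chol2inv_safe(info_post)
  score <- drop(Bt %*% (dN - p_spike))
  mean_post <- pred$mean + drop(cov_post %*% score)
  gaussian_belief(mean_post, cov_post)
}

# inverse with 1e-9 ridge fallback for (near-)singular matrices
chol2inv_safe <- function(S) {
  S <- (S + t(S)) / 2
  out <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(out)) {
    out <- solve(S + diag(1e-9, nrow(S)))
    out <- (out + t(out)) / 2
  }
  out
}

#' Gaussian-observation update (Kalman form of the filter)
#'
#' Information-form update of a predicted belief with a linear-Gaussian
#' observation `y = H x + e`, `e ~ N(0, R_obs)`.  Substituting this
#' observation model for the Bernoulli spike likelihood reduces the point
#' process filter to the Kalman filter, which is used as an independent
#' cross-check of the recursion structure.
#'
#' @param pred A `bmi_belief`.
#' @param y Observation vector.
#' @param H Observation matrix (length(y) x 6).
#' @param R_obs Observation noise covariance.
#' @return A `bmi_belief`.
#' @export
ppf_update_gaussian <- function(pred, y, H, R_obs) {
  Ri <- solve(R_obs)
  info_post <- chol2inv_safe(pred$cov) + t(H) %*% Ri %*% H
  cov_post <- chol2inv_safe(info_post)
  mean_post <- pred$mean +
    drop(cov_post %*% t(H) %*% Ri %*% (y - H %*% pred$mean))
  gaussian_belief(mean_post, cov_post)
}

# Bernoulli log-likelihood of one bin of ensemble spiking at state x
bin_loglik_at <- function(x, dN, model, bin_s) {
  lam <- rate_at(model, seq_along(model$alpha), x)
  p <- pmin(lam * bin_s, 0.999999)
  sum(dN * log(p) + (1 - dN) * log1p(-p))
}

#' Per-bin predictive log-likelihood of a duration-conditioned filter
#'
#' Laplace (Gaussian) approximation of
#' `log p(dN_t | N_{1:t-1}, T_i) = log int p(dN | x) N(x; pred) dx`,
#' assembled purely from the prediction and posterior moments the filter has
#' already computed:
#' `log p(dN | m_post) + log N(m_post; m_pred, Cov_pred)
#'  + 1/2 log det(2 pi Cov_post)`.
#' This is the quantity that drives the duration-mixture weights.
#'
#' @param pred A `bmi_belief` (prediction for this bin).
#' @param post A `bmi_belief` (posterior after [ppf_update()] on this bin).
#' @param dN Per-neuron spike indicators for this bin.
#' @param model A `bmi_kinematic_model`.
#' @param bin_s Bin width, s.
#' @return Scalar log predictive likelihood (`-Inf` if non-finite inputs
#'   make it undefined).
#' @export
duration_predictive_loglik <- function(pred, post, dN, model,
                                       bin_s = model$bin_s) {
  d <- length(pred$mean)
  ll_obs <- bin_loglik_at(post$mean, dN, model, bin_s)
  dev <- post$mean - pred$mean
  cov_pred <- pred$cov + diag(1e-12, d)
  cov_post <- post$cov + diag(1e-12, d)
  q <- tryCatch(drop(crossprod(dev, solve(cov_pred, dev))),
                error = function(e) Inf)
  ll_prior <- -0.5 * (q + d * log(2 * pi) + log_det_pd(cov_pred))
  ll_vol <- 0.5 * (d * log(2 * pi) + log_det_pd(cov_post))
  out <- ll_obs + ll_prior + ll_vol
  if (!is.finite(out)) -Inf else out
}

#' Duration grid for the parallel filter bank
#'
#' @param durations_s Increasing candidate movement durations, s.  The
#'   default coarse grid `{0.4, 0.6, 0.8, 1.0, 1.2}` spans natural reach
#'   times well inside the 3 s time-out.
#' @param bin_s Bin width, s.
#' @return Object of class `bmi_duration_grid`: list with `durations_s` and
#'   `bins` (integer horizons).
#' @export
duration_grid <- function(durations_s = c(0.4, 0.6, 0.8, 1.0, 1.2),
                          bin_s = 0.005) {
  durations_s <- sort(as.numeric(durations_s))
  if (length(durations_s) < 1L || any(diff(durations_s) <= 0))
    stop("durations must be strictly increasing", call. = FALSE)
  structure(list(durations_s = durations_s,
                 bins = as.integer(round(durations_s / bin_s)),
                 bin_s = bin_s),
            class = "bmi_duration_grid")
}

#' Initialize a feedback-controlled parallel filter bank
#'
#' Builds one FC-PPF per candidate duration, all targeting the (stage-1
#' decoded) target, with uniform initial duration weights.
#'
#' @param target_pos Decoded target position, length-2.
#' @param grid A `bmi_duration_grid`.
#' @param sys A `bmi_lti`.
#' @param cost_weights Named list/vector with `w_v`, `w_f`, `r` cost weights
#'   (see [cost_spec()]); defaults to the `cost_spec` defaults.
#' @param init Initial `bmi_belief` shared by all filters.
#' @return Object of class `bmi_filter_bank`.
#' @export
filter_bank <- function(target_pos, grid, sys, cost_weights = NULL,
                        init = gaussian_belief()) {
  stopifnot(inherits(grid, "bmi_duration_grid"))
  cw <- modifyList(list(w_v = formals(cost_spec)$w_v,
                        w_f = formals(cost_spec)$w_f,
                        r = formals(cost_spec)$r),
                   as.list(cost_weights %||% list()))
  filters <- lapply(grid$bins, function(Tb) {
    cost <- cost_spec(target_pos, Tb, w_v = cw$w_v, w_f = cw$w_f, r = cw$r)
    list(gains = solve_lqg(sys, cost), belief = init, T_bins = Tb)
  })
  structure(list(filters = filters, log_w = rep(-log(length(filters)),
                                                length(filters)),
                 active = rep(TRUE, length(filters)), t = 0L,
                 grid = grid),
            class = "bmi_filter_bank")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Advance the parallel filter bank by one bin
#'
#' For every active duration filter: prediction through its own
#' feedback-controlled prior (gains frozen at the terminal value past its
#' horizon for the longest filter), point-process update with the bin's
#' spikes, and multiplication of its mixture weight by the per-bin
#' predictive likelihood.  Filters whose horizon has elapsed drop out of
#' the mixture (the longest never does); weights are renormalized in log
#' space each bin.  The combined estimate is the weight-averaged posterior
#' mean.
#'
#' @param bank A `bmi_filter_bank`.
#' @param dN Per-neuron spike indicators for this bin.
#' @param sys A `bmi_lti`.
#' @param model A `bmi_kinematic_model`.
#' @param bin_s Bin width, s.
#' @return The updated bank, with elements `estimate` (combined 6-dim mean)
#'   and `weights` (per-duration mixture weights, zeros for inactive
#'   filters) refreshed.
#' @export
filter_bank_step <- function(bank, dN, sys, model, bin_s = model$bin_s) {
  t <- bank$t + 1L
  p <- length(bank$filters)
  # filters with elapsed horizons leave the mixture; the longest persists
  # past the grid with its terminal gain frozen
  active <- vapply(bank$filters, function(f) f$T_bins >= t, logical(1))
  if (!any(active)) active[p] <- TRUE
  dropped <- bank$active & !active
  bank$active <- active
  if (any(dropped)) {
    bank$log_w[!active] <- -Inf
    bank$log_w <- normalize_log_weights(bank$log_w, active)
  }
  ll <- rep(-Inf, p)
  for (i in which(active)) {
    f <- bank$filters[[i]]
    pred <- ppf_predict(f$belief, sys, gain_at(f$gains, t), f$gains$x_star)
    post <- ppf_update(pred, dN, model, bin_s)
    ll[i] <- duration_predictive_loglik(pred, post, dN, model, bin_s)
    bank$filters[[i]]$belief <- post
  }
  lw <- bank$log_w + ifelse(active, ll, -Inf)
  if (all(!is.finite(lw[active]))) {
    # total underflow: reset uniformly over the active filters
    lw[active] <- 0
  }
  bank$log_w <- normalize_log_weights(lw, active)
  w <- exp(bank$log_w)
  w[!active] <- 0
  means <- vapply(bank$filters, function(f) f$belief$mean, numeric(6))
  bank$estimate <- drop(means %*% w)
  bank$weights <- w
  bank$t <- t
  bank
}

normalize_log_weights <- function(lw, active) {
  m <- max(lw[active])
  if (!is.finite(m)) {
    lw[active] <- -log(sum(active))
    return(lw)
  }
  lw[active] <- lw[active] - (m + log(sum(exp(lw[active] - m))))
  lw
}

#' Decode a trial with the FC-P-PPF (duration-mixture filter)
#'
#' Runs the bank of duration-conditioned feedback-controlled point process
#' filters over the movement-epoch spikes of one trial, mixing them by
#' per-bin predictive likelihood.
#'
#' @param spikes Integer matrix, neurons x movement bins.
#' @param target_pos Decoded target position (from stage 1), length-2.
#' @param grid A `bmi_duration_grid`.
#' @param sys A `bmi_lti`.
#' @param model A `bmi_kinematic_model`.
#' @param cost_weights Optional cost-weight overrides (see [filter_bank()]).
#' @param init Initial belief.
#' @return List with `states` (bins x 6 combined posterior means),
#'   `weights` (bins x durations mixture-weight history) and the final
#'   `bank`.
#' @export
fc_p_ppf_decode <- function(spikes, target_pos, grid, sys, model,
                            cost_weights = NULL, init = gaussian_belief()) {
  spikes <- as.matrix(spikes)
  n_bins <- ncol(spikes)
  bank <- filter_bank(target_pos, grid, sys, cost_weights, init)
  states <- matrix(0, n_bins, 6)
  weights <- matrix(0, n_bins, length(bank$filters))
  for (t in seq_len(n_bins)) {
    bank <- filter_bank_step(bank, spikes[, t], sys, model)
    states[t, ] <- bank$estimate
    weights[t, ] <- bank$weights
  }
  list(states = states, weights = weights, bank = bank)
}

#' Decode a trial with a single-duration FC-PPF
#'
#' @param spikes Integer matrix, neurons x movement bins.
#' @param gains A `bmi_gains` for the assumed duration (terminal gain frozen
#'   past the horizon).
#' @param sys A `bmi_lti`.
#' @param model A `bmi_kinematic_model`.
#' @param init Initial belief.
#' @return List with `states` (bins x 6 posterior means) and the final
#'   `belief`.
#' @export
fc_ppf_decode <- function(spikes, gains, sys, model,
                          init = gaussian_belief()) {
  spikes <- as.matrix(spikes)
  n_bins <- ncol(spikes)
  states <- matrix(0, n_bins, 6)
  belief <- init
  for (t in seq_len(n_bins)) {
    pred <- ppf_predict(belief, sys, gain_at(gains, t), gains$x_star)
    belief <- ppf_update(pred, spikes[, t], model)
    states[t, ] <- belief$mean
  }
  list(states = states, belief = belief)
}

#' Decode a trial with the random-walk PPF ablation
#'
#' Removes the control input from the prior (`B = 0`): the state model
#' becomes a smoothness-only random walk and the filter uses no target
#' information.  Identical to the FC-PPF recursions with zero control.
#'
#' @param spikes Integer matrix, neurons x movement bins.
#' @param sys A `bmi_lti` (its `A` and `W` are kept; `B` is ignored).
#' @param model A `bmi_kinematic_model`.
#' @param init Initial belief.
#' @return List with `states` (bins x 6 posterior means) and the final
#'   `belief`.
#' @export
rw_ppf_decode <- function(spikes, sys, model, init = gaussian_belief()) {
  spikes <- as.matrix(spikes)
  n_bins <- ncol(spikes)
  states <- matrix(0, n_bins, 6)
  belief <- init
  for (t in seq_len(n_bins)) {
    pred <- ppf_predict(belief, sys, NULL)
    belief <- ppf_update(pred, spikes[, t], model)
    states[t, ] <- belief$mean
  }
  list(states = states, belief = belief)
}
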