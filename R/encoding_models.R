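#' Fit the delay-period target rate model
#'
#' Models each neuron's delay-period spiking as a homogeneous Poisson process
#' whose constant rate depends on the cued target.  The maximum-likelihood
#' rate for a (neuron, target) pair is the total spike count in the decoding
#' window (the last `delay_window_ms` before the go cue) divided by the total
#' exposure, floored at `rate_floor` so that downstream log-likelihoods stay
#' finite.  This equals a Poisson GLM with log link and target-indicator
#' design, up to the floor.
#'
#' @param records List of `bmi_trial_record`s (every target must appear).
#' @param config A `bmi_task_config`.
#' @param rate_floor Minimum fitted rate, spikes/s.
#' @return An object of class `bmi_target_rate_model`: list with `rates`
#'   (neurons x targets, spikes/s), `exposure_s` (per-target fitting
#'   exposure, s) and `rate_floor`.
#' @export
fit_target_model <- function(records, config, rate_floor = 0.1) {
  stopifnot(length(records) > 0)
  targets <- vapply(records, function(r) r$cued_target, 0L)
  missing <- setdiff(seq_len(config$n_targets), unique(targets))
  if (length(missing))
    stop("no trials for target(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n_neurons <- nrow(records[[1]]$spikes)
  bin_s <- config$bin_ms / 1000
  counts <- matrix(0, n_neurons, config$n_targets)
  exposure <- numeric(config$n_targets)
  for (r in records) {
    w <- delay_window_spikes(r, config)
    counts[, r$cued_target] <- counts[, r$cued_target] + rowSums(w)
    exposure[r$cued_target] <- exposure[r$cued_target] + ncol(w) * bin_s
  }
  rates <- sweep(counts, 2, exposure, "/")
  rates <- pmax(rates, rate_floor)
  structure(list(rates = rates, exposure_s = exposure, rate_floor = rate_floor),
            class = "bmi_target_rate_model")
}

# damped Poisson IRLS with offset; returns coefficients, standard errors and
# convergence flag.  X excludes the intercept column.
poisson_irls <- function(X, y, offset, tol = 1e-8, max_iter = 100,
                         ridge = 1e-6) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- c(log(max(mean(y), 1e-8)) - mean(offset), rep(0, p - 1L))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta) + offset
    eta <- pmin(eta, 30)             # guard exp overflow
    mu <- exp(eta)
    z <- (y - mu)
    H <- crossprod(Xd, Xd * mu) + diag(ridge, p)
    step <- tryCatch(solve(H, crossprod(Xd, z)), error = function(e) NULL)
    if (is.null(step)) return(list(ok = FALSE))
    beta_new <- beta + drop(step)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  eta <- pmin(drop(Xd %*% beta) + offset, 30)
  mu <- exp(eta)
  H <- crossprod(Xd, Xd * mu) + diag(ridge, p)
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov)) return(list(ok = FALSE))
  list(ok = converged && all(is.finite(beta)), beta = beta,
       se = sqrt(pmax(diag(cov), 0)))
}

#' Fit the peri-movement kinematic tuning model
#'
#' Fits, per neuron, a point-process (Poisson GLM, log link) model of the
#' movement-epoch spiking with instantaneous rate
#' `lambda(t) = exp(alpha + beta' (p_x, p_y, v_x, v_y))` — a log-linear
#' modification of cosine tuning.  Covariates are standardized internally
#' for conditioning and coefficients reported in native units.  Coefficient
#' p-values come from the asymptotic normal theory of the fit; significance
#' uses a Bonferroni correction across all (neuron, coefficient) tests at
#' family level `alpha_level`.  Each neuron is classified as
#' `position_only`, `velocity_only`, `both` or `untuned`.
#'
#' @param records List of `bmi_trial_record`s with movement epochs.
#' @param bin_s Bin width, s.
#' @param alpha_level Family-wise significance level (default 0.05).
#' @return List with components `model` (class `bmi_kinematic_model`: `alpha`
#'   per neuron, `beta` neurons x 4) and `stats` (class `bmi_tuning_stats`:
#'   `p_values` and asymptotic `se` (native units), both neurons x 4,
#'   `significant` logical neurons x 4 after Bonferroni, `category` and
#'   `converged` per neuron).
#' @export
fit_kinematic_model <- function(records, bin_s = 0.005, alpha_level = 0.05) {
  mov <- lapply(records, movement_epoch)
  X <- do.call(rbind, lapply(mov, function(m) m$kinematics[, 1:4, drop = FALSE]))
  Y <- do.call(cbind, lapply(mov, function(m) m$spikes))
  n_neurons <- nrow(Y)
  mu_x <- colMeans(X)
  sd_x <- apply(X, 2, stats::sd)
  sd_x[sd_x < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  offset <- rep(log(bin_s), nrow(Xs))
  alpha <- numeric(n_neurons)
  beta <- matrix(0, n_neurons, 4,
                 dimnames = list(NULL, c("p_x", "p_y", "v_x", "v_y")))
  se <- matrix(Inf, n_neurons, 4, dimnames = dimnames(beta))
  pv <- matrix(1, n_neurons, 4, dimnames = dimnames(beta))
  converged <- logical(n_neurons)
  for (c_i in seq_len(n_neurons)) {
    fit <- poisson_irls(Xs, Y[c_i, ], offset)
    if (!isTRUE(fit$ok)) next
    converged[c_i] <- TRUE
    b_std <- fit$beta[-1]
    beta[c_i, ] <- b_std / sd_x
    se[c_i, ] <- fit$se[-1] / sd_x
    alpha[c_i] <- fit$beta[1] - sum(b_std * mu_x / sd_x)
    z <- b_std / pmax(fit$se[-1], 1e-300)
    pv[c_i, ] <- 2 * stats::pnorm(-abs(z))
  }
  n_tests <- n_neurons * 4L
  sig <- pv < alpha_level / n_tests
  sig[!converged, ] <- FALSE
  category <- vapply(seq_len(n_neurons), function(i) {
    pos <- any(sig[i, 1:2]); vel <- any(sig[i, 3:4])
    if (pos && vel) "both" else if (pos) "position_only"
    else if (vel) "velocity_only" else "untuned"
  }, character(1))
  list(
    model = structure(list(alpha = alpha, beta = beta, bin_s = bin_s),
                      class = "bmi_kinematic_model"),
    stats = structure(list(p_values = pv, se = se, significant = sig,
                           category = category, converged = converged,
                           alpha_level = alpha_level),
                      class = "bmi_tuning_stats")
  )
}

#' Construct a kinematic tuning model from known parameters
#'
#' @param alpha Per-neuron log baseline rate (log spikes/s at the origin).
#' @param beta Neurons x 4 matrix of log-rate gradients over
#'   `(p_x, p_y, v_x, v_y)`.
#' @param bin_s Bin width, s.
#' @return A `bmi_kinematic_model`.
#' @export
kinematic_model <- function(alpha, beta, bin_s = 0.005) {
  beta <- as.matrix(beta)
  stopifnot(length(alpha) == nrow(beta), ncol(beta) == 4L)
  structure(list(alpha = as.numeric(alpha), beta = beta, bin_s = bin_s),
            class = "bmi_kinematic_model")
}

#' Conditional intensity of a neuron at a kinematic state
#'
#' Evaluates `lambda = exp(alpha + beta' (p_x, p_y, v_x, v_y))`, clamped so
#' that the per-bin event probability `lambda * bin_s` never exceeds
#' `max_prob` (0.95 by default), keeping the Bernoulli approximation of the
#' point process valid.
#'
#' @param model A `bmi_kinematic_model`.
#' @param neuron Neuron index, or a vector of indices.
#' @param x Kinematic state: any vector whose first four elements are
#'   `(p_x, p_y, v_x, v_y)` (a full 6-dim state is accepted).
#' @param max_prob Clamp on `lambda * bin_s`.
#' @return Rate(s) in spikes/s.
#' @export
rate_at <- function(model, neuron = seq_along(model$alpha), x,
                    max_prob = 0.95) {
  xk <- as.numeric(x)[1:4]
  eta <- model$alpha[neuron] + drop(model$beta[neuron, , drop = FALSE] %*% xk)
  pmin(exp(eta), max_prob / model$bin_s)
}
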