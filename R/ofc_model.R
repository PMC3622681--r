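#' Muscle-like plant parameters
#'
#' Parameters of the second-order point-mass plant with a first-order
#' low-pass muscle stage used as the forward model of the reach: in each
#' spatial dimension the continuous dynamics are
#' `p' = v`, `v' = (f - b v) / m`, `f' = (u - f) / tau`.
#' The defaults (`b` = 10 N s/m, `tau` = 40 ms, `m` = 1 kg) are the standard
#' biomechanical values for planar reaching.
#'
#' @param b Viscosity, N s/m.
#' @param tau Muscle low-pass time constant, s.
#' @param m Effective mass, kg.
#' @param dt Discretization step, s (the 5 ms spike bin).
#' @return An object of class `bmi_plant_params`.
#' @export
plant_params <- function(b = 10, tau = 0.040, m = 1, dt = 0.005) {
  vals <- c(b = b, tau = tau, m = m, dt = dt)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all plant parameters must be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "bmi_plant_params")
}

# state layout of the 6-vector: (p_x, p_y, v_x, v_y, f_x, f_y);
# per-dimension index sets interleave as {1,3,5} and {2,4,6}
dim_idx <- function(d) c(d, d + 2L, d + 4L)

#' Discretize the reach plant by zero-order hold
#'
#' Builds the discrete-time linear system `x_t = A x_{t-1} + B u_t + w_t`
#' over the 6-dimensional kinematic state from the continuous muscle-like
#' plant, using the exact zero-order-hold discretization (matrix
#' exponential of the augmented system).  Process noise enters on the force
#' channels only: `W = diag(0, 0, 0, 0, sigma_f^2, sigma_f^2)`.
#'
#' @param p A `bmi_plant_params`.
#' @param sigma_f Per-step standard deviation of the force noise, N.  The
#'   default [default_sigma_f()] is calibrated so that noisy feedback
#'   rollouts acquire the default target disk on roughly 90% of reaches.
#' @return An object of class `bmi_lti`: list with `A` (6x6), `B` (6x2),
#'   `W` (6x6) and the originating `params`.
#' @export
discretize_plant <- function(p, sigma_f = default_sigma_f()) {
  stopifnot(inherits(p, "bmi_plant_params"))
  Ac <- matrix(c(0, 1, 0,
                 0, -p$b / p$m, 1 / p$m,
                 0, 0, -1 / p$tau), 3, 3, byrow = TRUE)
  Bc <- matrix(c(0, 0, 1 / p$tau), 3, 1)
  # ZOH: exp([[Ac, Bc], [0, 0]] * dt) packs Ad and Bd
  aug <- rbind(cbind(Ac, Bc), 0)
  ead <- as.matrix(Matrix::expm(aug * p$dt))
  Ad1 <- ead[1:3, 1:3]
  Bd1 <- ead[1:3, 4, drop = FALSE]
  A <- matrix(0, 6, 6)
  B <- matrix(0, 6, 2)
  for (d in 1:2) {
    A[dim_idx(d), dim_idx(d)] <- Ad1
    B[dim_idx(d), d] <- Bd1
  }
  W <- diag(c(0, 0, 0, 0, sigma_f^2, sigma_f^2))
  structure(list(A = A, B = B, W = W, params = p), class = "bmi_lti")
}

#' Default force-noise scale of the prior model
#'
#' Per-step force noise standard deviation used in the feedback-controlled
#' prior.  The value is fixed by the behavioral calibration of the
#' simulator: with the default task geometry, cost weights and movement
#' durations drawn from the default grid, noisy unassisted rollouts run
#' under the task protocol score as successes on approximately 90% of
#' reaches ([calibrate_state_noise()] reproduces this number).
#'
#' @return Numeric scalar, N.
#' @export
default_sigma_f <- function() 3.18

#' Quadratic reach cost specification
#'
#' The reach cost is
#' `J = sum_t u_t' R u_t + (x_T - x*)' Q_T (x_T - x*)` with
#' `Q_T = diag(1, 1, w_v, w_v, w_f, w_f)` and `R = r I`: unit weight on the
#' terminal position error, `w_v` on terminal velocity (stopping), `w_f` on
#' terminal force (relaxation), and a running control-effort penalty.  The
#' goal state is `x* = (d*, 0, 0)`.  The default weights are set for the
#' default task scale (0.1-unit reach) so that noiseless closed-loop
#' rollouts are straight, terminally accurate (within a fraction of the
#' target radius) and carry a bell-shaped speed profile;
#' [calibrate_weights()] offers an alternative, behavior-driven weighting.
#'
#' @param target Target position `d*`, numeric length-2.
#' @param T_bins Movement horizon in bins (>= 2).
#' @param w_v Terminal velocity weight.
#' @param w_f Terminal force weight.
#' @param r Control effort weight (scalar; `R = r I2`).
#' @return An object of class `bmi_cost_spec`.
#' @export
cost_spec <- function(target, T_bins, w_v = 1e-2, w_f = 1e-4, r = 1e-7) {
  target <- as.numeric(target)
  T_bins <- as.integer(T_bins)
  if (length(target) != 2L) stop("target must be a 2-vector", call. = FALSE)
  if (is.na(T_bins) || T_bins < 2L) stop("horizon T_bins must be >= 2", call. = FALSE)
  if (w_v < 0 || w_f < 0) stop("terminal weights must be >= 0", call. = FALSE)
  if (!(r > 0)) stop("control weight r must be > 0 (R positive definite)", call. = FALSE)
  structure(list(target = target, T_bins = T_bins, w_v = w_v, w_f = w_f, r = r),
            class = "bmi_cost_spec")
}

terminal_Q <- function(cost) diag(c(1, 1, cost$w_v, cost$w_v, cost$w_f, cost$w_f))

x_star_of <- function(cost) c(cost$target, 0, 0, 0, 0)

#' Finite-horizon LQG feedback gains
#'
#' Solves the finite-horizon linear-quadratic regulator by the backward
#' Riccati recursion and returns the time-varying feedback gains of the
#' optimal control law `u_t = -L_t (x_{t-1} - x*)`.  With a terminal-only
#' state cost the gains can be precomputed offline once per (target,
#' duration) pair and reused in real time.
#'
#' @param sys A `bmi_lti`.
#' @param cost A `bmi_cost_spec`.
#' @return An object of class `bmi_gains`: list with `L` (list of `T_bins`
#'   2x6 matrices), `x_star` and `T_bins`.
#' @export
solve_lqg <- function(sys, cost) {
  stopifnot(inherits(sys, "bmi_lti"), inherits(cost, "bmi_cost_spec"))
  A <- sys$A; B <- sys$B
  R <- diag(cost$r, 2)
  S <- terminal_Q(cost)
  L <- vector("list", cost$T_bins)
  for (t in cost$T_bins:1) {
    G <- R + crossprod(B, S %*% B)
    Gi <- tryCatch(solve(G), error = function(e)
      stop(sprintf("singular control Hessian at step %d", t), call. = FALSE))
    L[[t]] <- Gi %*% crossprod(B, S %*% A)
    S <- crossprod(A, S %*% (A - B %*% L[[t]]))
    S <- (S + t(S)) / 2
  }
  structure(list(L = L, x_star = x_star_of(cost), T_bins = cost$T_bins),
            class = "bmi_gains")
}

# gain at step t with the terminal gain frozen past the horizon
gain_at <- function(gains, t) {
  gains$L[[min(t, gains$T_bins)]]
}

#' Simulate the feedback-controlled prior model
#'
#' Rolls out the closed-loop state-space model
#' `x_t = A x_{t-1} + B u_t + w_t`, `u_t = -L_t (x_{t-1} - x*)`.
#' This is the trajectory prior of the decoder: noiseless rollouts are
#' straight reaches with bell-shaped speed profiles.
#'
#' @param sys A `bmi_lti`.
#' @param gains A `bmi_gains`.
#' @param x0 Initial 6-dim state (default: at rest at the origin).
#' @param n_steps Number of steps; defaults to the gain horizon.  Steps past
#'   the horizon reuse the terminal gain.
#' @param noise Logical; add force noise `w_t ~ N(0, W)` (uses the current
#'   RNG state).
#' @return List with `x` (`n_steps` + 1 x 6 state matrix, first row `x0`)
#'   and `u` (`n_steps` x 2 control matrix).
#' @export
rollout_prior <- function(sys, gains, x0 = numeric(6), n_steps = gains$T_bins,
                          noise = TRUE) {
  stopifnot(inherits(sys, "bmi_lti"), inherits(gains, "bmi_gains"))
  x0 <- as.numeric(x0)
  if (length(x0) != 6L) stop("x0 must be a 6-vector", call. = FALSE)
  sd_f <- sqrt(diag(sys$W)[5:6])
  X <- matrix(0, n_steps + 1L, 6)
  U <- matrix(0, n_steps, 2)
  X[1, ] <- x0
  x <- x0
  for (t in seq_len(n_steps)) {
    u <- -gain_at(gains, t) %*% (x - gains$x_star)
    x <- sys$A %*% x + sys$B %*% u
    if (noise) x[5:6] <- x[5:6] + stats::rnorm(2, 0, sd_f)
    X[t + 1L, ] <- x
    U[t, ] <- u
  }
  list(x = X, u = U)
}

# average of the four cost terms over noisy rollouts (raw, unweighted)
rollout_cost_terms <- function(sys, cost, gains, n_rollouts) {
  terms <- matrix(0, n_rollouts, 4)
  xs <- x_star_of(cost)
  for (i in seq_len(n_rollouts)) {
    ro <- rollout_prior(sys, gains, n_steps = cost$T_bins, noise = TRUE)
    xT <- ro$x[cost$T_bins + 1L, ]
    terms[i, ] <- c(sum((xT[1:2] - xs[1:2])^2),   # terminal position error
                    sum(xT[3:4]^2),               # terminal velocity
                    sum(xT[5:6]^2),               # terminal force
                    sum(ro$u^2))                  # control effort
  }
  colMeans(terms)
}

#' Balance the reach cost weights by Monte Carlo rollouts
#'
#' Rescales the terminal velocity and force weights and the control-effort
#' weight so that the Monte-Carlo averages of the four cost terms (terminal
#' position error, weighted terminal velocity, weighted terminal force,
#' control effort) over noisy closed-loop rollouts are approximately equal —
#' within a factor of `tol_factor` of each other.  The position term keeps
#' unit weight; only the ratios matter for the gains.  The search runs an
#' outer bisection on the control weight (the effort-to-position ratio is
#' monotone in it) with a damped inner matching of `w_v` and `w_f`.
#'
#' With purely additive motor noise, parity between control effort and
#' terminal position error is only reachable by tolerating a slack reach;
#' the balanced weights therefore describe a low-effort movement regime
#' rather than the terminally accurate default prior of [cost_spec()].
#'
#' @param sys A `bmi_lti`.
#' @param cost_template A `bmi_cost_spec` providing the target, horizon and
#'   starting weights.
#' @param n_rollouts Rollouts per iteration.
#' @param seed Integer seed (the procedure is deterministic given the seed).
#' @param max_iter Maximum fixed-point iterations.
#' @param tol_factor Acceptable max/min ratio of the averaged weighted terms.
#' @return A `bmi_cost_spec` with balanced weights; attribute `converged`
#'   (logical) and `balance` (the final max/min ratio).
#' @export
calibrate_weights <- function(sys, cost_template, n_rollouts = 200, seed = 1,
                              max_iter = 25, tol_factor = 2) {
  stopifnot(inherits(cost_template, "bmi_cost_spec"))
  seed <- as.integer(seed)
  eps <- .Machine$double.xmin

  # weighted term averages at given weights (seeded, deterministic)
  measure <- function(cost) {
    gains <- solve_lqg(sys, cost)
    set.seed(seed)
    raw <- rollout_cost_terms(sys, cost, gains, n_rollouts)
    raw * c(1, cost$w_v, cost$w_f, cost$r)
  }
  # damped inner matching of w_v, w_f to the position term at fixed r
  inner <- function(cost, n_it = 6) {
    for (k in seq_len(n_it)) {
      wt <- measure(cost)
      ratios <- wt[1] / pmax(wt[2:3], eps)
      if (max(ratios, 1 / ratios) <= sqrt(tol_factor)) break
      cost$w_v <- cost$w_v * sqrt(max(ratios[1], eps))
      cost$w_f <- cost$w_f * sqrt(max(ratios[2], eps))
    }
    cost
  }
  balance_of <- function(wt) max(wt) / max(min(wt), eps)

  cost <- inner(cost_template)
  wt <- measure(cost)
  if (balance_of(wt) > tol_factor) {
    # the effort-vs-position ratio is monotone in log r: bisect on it,
    # re-matching w_v / w_f at each candidate r
    g_of <- function(cost) { wt <- measure(cost); log(wt[1] / max(wt[4], eps)) }
    lo <- cost; lo$r <- cost$r * 1e-3
    hi <- cost; hi$r <- cost$r * 1e+3
    iter <- 0L
    while (g_of(lo) > 0 && iter < 4L) { lo$r <- lo$r * 1e-2; iter <- iter + 1L }
    iter <- 0L
    while (g_of(hi) < 0 && iter < 4L) { hi$r <- hi$r * 1e+2; iter <- iter + 1L }
    for (it in seq_len(max_iter)) {
      mid <- cost; mid$r <- sqrt(lo$r * hi$r)
      mid <- inner(mid)
      wt <- measure(mid)
      cost <- mid
      if (balance_of(wt) <= tol_factor) break
      if (log(wt[1] / max(wt[4], eps)) > 0) hi$r <- mid$r else lo$r <- mid$r
    }
  }
  balance <- balance_of(wt)
  attr(cost, "converged") <- balance <= tol_factor
  attr(cost, "balance") <- balance
  if (balance > tol_factor)
    warning("cost-weight calibration did not reach the balance tolerance")
  cost
}

#' Calibrate the force-noise scale to reach behavior
#'
#' Finds the force-noise standard deviation at which noisy closed-loop
#' rollouts, run under the task protocol (continued past the intended
#' horizon with the terminal gain frozen, up to the task time-out), score
#' as task successes — enter the cued target disk first, without touching
#' an incorrect disk — on a requested fraction of unassisted reaches.
#' Scoring against the full task rules makes the calibration respect both
#' endpoint scatter and lateral excursions into neighboring disks.
#' Monotone bisection on `sigma_f`.
#'
#' @param plant A `bmi_plant_params`.
#' @param cost A `bmi_cost_spec`, or a list of them (e.g. one per duration
#'   of the default grid); rollouts draw uniformly among them, emulating
#'   the subject's choice of movement duration.
#' @param config A `bmi_task_config` (target radius and time-out).
#' @param reach_rate Desired success fraction (default 0.9).
#' @param n_rollouts Rollouts per evaluation.
#' @param seed Integer seed.
#' @return Calibrated `sigma_f`, numeric scalar.
#' @export
calibrate_state_noise <- function(plant, cost, config, reach_rate = 0.9,
                                  n_rollouts = 200, seed = 1) {
  costs <- if (inherits(cost, "bmi_cost_spec")) list(cost) else cost
  eb <- epoch_bins(config)
  centers <- target_centers(config)
  hit_rate <- function(sigma_f) {
    sys <- discretize_plant(plant, sigma_f = sigma_f)
    gains <- lapply(costs, solve_lqg, sys = sys)
    cued <- vapply(costs, function(cs)
      which.min(rowSums(sweep(centers, 2, cs$target)^2)), 0L)
    set.seed(as.integer(seed))
    hits <- vapply(seq_len(n_rollouts), function(i) {
      j <- sample.int(length(costs), 1L)
      ro <- rollout_prior(sys, gains[[j]], n_steps = eb$timeout, noise = TRUE)
      score_trial(ro$x[-1, 1:2, drop = FALSE], config, cued[j])$success
    }, logical(1))
    mean(hits)
  }
  lo <- 1e-3; hi <- 64
  for (i in 1:18) {
    mid <- sqrt(lo * hi)
    if (hit_rate(mid) >= reach_rate) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}
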