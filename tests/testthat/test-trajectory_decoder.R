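toy_kin_model <- function(alpha = log(4), beta = c(4, 0, 0, 0)) {
  kinematic_model(alpha, matrix(beta, 1, 4))
}

test_that("prediction with no observations traces the prior path to the target", {
  sys <- discretize_plant(default_plant)
  g <- solve_lqg(sys, cost_spec(c(0.1, 0), 120))
  b <- gaussian_belief()
  pos <- matrix(0, 120, 2)
  for (t in 1:120) {
    b <- ppf_predict(b, sys, g$L[[t]], g$x_star)
    pos[t, ] <- b$mean[1:2]
  }
  # straight line to the decoded target
  expect_lt(max(abs(pos[, 2])), 0.02 * 0.1)
  expect_lt(abs(pos[120, 1] - 0.1), 0.005)
  # identical to the noiseless rollout of the prior
  ro <- rollout_prior(sys, g, noise = FALSE)
  expect_equal(pos, ro$x[-1, 1:2], tolerance = 1e-10)
})

test_that("the goal with zero covariance is a fixed point when W = 0", {
  sys <- discretize_plant(default_plant, sigma_f = 0)
  g <- solve_lqg(sys, cost_spec(c(0.1, 0), 50))
  b <- gaussian_belief(mean = g$x_star, cov = matrix(0, 6, 6))
  b2 <- ppf_predict(b, sys, g$L[[1]], g$x_star)
  expect_equal(b2$mean, g$x_star, tolerance = 1e-12)
  expect_equal(max(abs(b2$cov)), 0)
})

test_that("predicted covariance equals the closed-loop Lyapunov step", {
  sys <- discretize_plant(default_plant)
  g <- solve_lqg(sys, cost_spec(c(0.1, 0), 30))
  S0 <- diag(c(1, 2, 3, 4, 5, 6)) * 1e-4
  b <- gaussian_belief(mean = c(0.01, 0, 0.1, 0, 0.2, 0), cov = S0)
  out <- ppf_predict(b, sys, g$L[[5]], g$x_star)
  Acl <- sys$A - sys$B %*% g$L[[5]]
  expect_equal(out$cov, Acl %*% S0 %*% t(Acl) + sys$W, tolerance = 1e-10)
  u <- -g$L[[5]] %*% (b$mean - g$x_star)
  expect_equal(out$mean, drop(sys$A %*% b$mean + sys$B %*% u),
               tolerance = 1e-12)
})

test_that("updating with zero neurons returns the prediction exactly", {
  m0 <- kinematic_model(numeric(0), matrix(0, 0, 4))
  pred <- gaussian_belief(mean = c(0.02, 0, 0, 0, 0, 0), cov = diag(1e-4, 6))
  post <- ppf_update(pred, integer(0), m0)
  expect_identical(post, pred)
})

test_that("ppf update matches a dense-grid Bayes oracle in a 1-D toy", {
  # small lambda dt regime where the Laplace posterior is near-exact
  km <- toy_kin_model(alpha = log(4), beta = c(4, 0, 0, 0))
  pred <- gaussian_belief(mean = c(0.05, 0, 0, 0, 0, 0),
                          cov = diag(c(1e-4, rep(1e-12, 5))))
  xs <- seq(-0.1, 0.2, length.out = 60001)
  for (dN in c(1L, 0L)) {
    post <- ppf_update(pred, dN, km)
    lam <- pmin(exp(log(4) + 4 * xs), 0.95 / 0.005)
    lik <- if (dN == 1L) lam * 0.005 else 1 - lam * 0.005
    pr <- stats::dnorm(xs, 0.05, 0.01) * lik
    Z <- sum(pr); m <- sum(xs * pr) / Z; v <- sum((xs - m)^2 * pr) / Z
    expect_equal(post$mean[1], m, tolerance = 1e-3)
    expect_equal(post$cov[1, 1], v, tolerance = 1e-3)
    # a spike from a +x tuned cell moves the mean in +x, no spike in -x
    if (dN == 1L) expect_gt(post$mean[1], pred$mean[1])
    else expect_lt(post$mean[1], pred$mean[1])
  }
})

test_that("posterior covariance never exceeds the prediction covariance", {
  set.seed(14)
  km <- kinematic_model(log(stats::runif(6, 2, 10)),
                        matrix(stats::rnorm(24, 0, 3), 6, 4))
  b <- gaussian_belief(cov = diag(1e-3, 6))
  sys <- discretize_plant(default_plant)
  g <- solve_lqg(sys, cost_spec(c(0.1, 0), 100))
  for (t in 1:60) {
    pred <- ppf_predict(b, sys, g$L[[t]], g$x_star)
    b <- ppf_update(pred, rbinom(6, 1, 0.1), km)
    ev <- eigen(pred$cov - b$cov, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
  }
})

test_that("the duration predictive likelihood matches numerical quadrature", {
  km <- toy_kin_model(alpha = log(4), beta = c(4, 0, 0, 0))
  pred <- gaussian_belief(mean = c(0.05, 0, 0, 0, 0, 0),
                          cov = diag(c(1e-4, rep(1e-12, 5))))
  xs <- seq(-0.15, 0.25, length.out = 60001)
  for (dN in c(1L, 0L)) {
    post <- ppf_update(pred, dN, km)
    ll <- duration_predictive_loglik(pred, post, dN, km)
    lam <- pmin(exp(log(4) + 4 * xs), 0.95 / 0.005)
    lik <- if (dN == 1L) lam * 0.005 else 1 - lam * 0.005
    quad <- log(sum(stats::dnorm(xs, 0.05, 0.01) * lik) * (xs[2] - xs[1]))
    expect_equal(ll, quad, tolerance = 1e-2)
  }
})

test_that("an untuned ensemble leaves duration weights untouched", {
  km <- kinematic_model(log(c(5, 8)), matrix(0, 2, 4))
  bank <- filter_bank(c(0.1, 0), default_grid, default_sys)
  set.seed(15)
  for (t in 1:60) {
    bank <- filter_bank_step(bank, rbinom(2, 1, 0.03), default_sys, km)
    w <- bank$weights[bank$active]
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(diff(range(w)), 0, tolerance = 1e-9)
  }
})

test_that("log-weight normalization is translation invariant", {
  lw <- c(-500, -502, -510, -Inf)
  act <- c(TRUE, TRUE, TRUE, FALSE)
  n1 <- ofcbmi:::normalize_log_weights(lw, act)
  n2 <- ofcbmi:::normalize_log_weights(lw + 123.4, act)
  expect_equal(n1[act], n2[act], tolerance = 1e-12)
  expect_equal(sum(exp(n1[act])), 1, tolerance = 1e-12)
})

test_that("a singleton duration grid reduces the mixture to one FC-PPF", {
  w <- sim_world()
  km <- w$kin_fit$model
  rec <- w$train$records[[3]]
  m <- movement_epoch(rec)
  tg <- target_centers(default_cfg)[rec$cued_target, ]
  g1 <- duration_grid(0.6)
  mix <- fc_p_ppf_decode(m$spikes, tg, g1, default_sys, km)
  gains <- solve_lqg(default_sys, cost_spec(tg, 120))
  single <- fc_ppf_decode(m$spikes, gains, default_sys, km)
  expect_equal(mix$states, single$states, tolerance = 1e-10)
  expect_true(all(abs(mix$weights - 1) < 1e-12))
})

test_that("mixture weights sum to one after every bin", {
  w <- sim_world()
  km <- w$kin_fit$model
  rec <- w$train$records[[5]]
  m <- movement_epoch(rec)
  tg <- target_centers(default_cfg)[rec$cued_target, ]
  out <- fc_p_ppf_decode(m$spikes, tg, default_grid, default_sys, km)
  expect_true(all(abs(rowSums(out$weights) - 1) < 1e-10))
})

test_that("rw filter equals the fc filter with control removed", {
  w <- sim_world()
  km <- w$kin_fit$model
  m <- movement_epoch(w$train$records[[7]])
  rw <- rw_ppf_decode(m$spikes, default_sys, km)
  # FC-PPF with B = 0 and zero gains is definitionally the same recursion
  sys0 <- default_sys; sys0$B <- matrix(0, 6, 2)
  gains0 <- list(L = rep(list(matrix(0, 2, 6)), ncol(m$spikes)),
                 x_star = numeric(6), T_bins = ncol(m$spikes))
  class(gains0) <- "bmi_gains"
  fc <- fc_ppf_decode(m$spikes, gains0, sys0, km)
  expect_identical(rw$states, fc$states)
})

test_that("with no spikes and vanishing noise the rw estimate stays put", {
  sys0 <- discretize_plant(default_plant, sigma_f = 1e-9)
  km <- toy_kin_model(alpha = log(0.1))
  init <- gaussian_belief(mean = c(0.03, -0.02, 0, 0, 0, 0),
                          cov = diag(1e-8, 6))
  out <- rw_ppf_decode(matrix(0L, 1, 100), sys0, km, init)
  expect_lt(max(abs(sweep(out$states[, 1:2], 2, init$mean[1:2]))), 1e-3)
})

test_that("fc-ppf with true target beats rw-ppf on simulated reaches", {
  w <- sim_world()
  km <- w$kin_fit$model
  wins <- 0; n_runs <- 30
  g <- w$gain_cache[[1]][[2]]      # target 1, 0.6 s
  for (k in seq_len(n_runs)) {
    set.seed(700 + k)
    ro <- rollout_prior(default_sys, g, n_steps = 120, noise = TRUE)
    sp <- vapply(1:120, function(t) ofcbmi:::draw_spikes(
      rate_at(w$pop$kin_model, seq_along(w$pop$baseline), ro$x[t + 1, ]),
      0.005), integer(length(w$pop$baseline)))
    truth <- ro$x[-1, 1:2]
    fc <- fc_ppf_decode(sp, g, default_sys, km)
    rw <- rw_ppf_decode(sp, default_sys, km)
    wins <- wins +
      (rms_error(rw$states[, 1:2], truth) > rms_error(fc$states[, 1:2], truth))
  }
  expect_gt(wins / n_runs, 0.5)
})

test_that("with gaussian observations the filter recursion is a kalman filter", {
  # independent oracle: textbook covariance-form Kalman filter
  sys <- discretize_plant(default_plant)
  g <- solve_lqg(sys, cost_spec(c(0.1, 0), 80))
  H <- rbind(c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0))
  R_obs <- diag(1e-4, 2)
  set.seed(16)
  b <- gaussian_belief(cov = diag(1e-4, 6))
  m_k <- b$mean; P_k <- b$cov
  for (t in 1:40) {
    y <- c(0.001 * t, -0.0005 * t) + stats::rnorm(2, 0, 0.01)
    pred <- ppf_predict(b, sys, g$L[[t]], g$x_star)
    b <- ppf_update_gaussian(pred, y, H, R_obs)
    # oracle step
    u <- -g$L[[t]] %*% (m_k - g$x_star)
    m_p <- drop(sys$A %*% m_k + sys$B %*% u)
    Acl <- sys$A - sys$B %*% g$L[[t]]
    P_p <- Acl %*% P_k %*% t(Acl) + sys$W
    K <- P_p %*% t(H) %*% solve(H %*% P_p %*% t(H) + R_obs)
    m_k <- m_p + drop(K %*% (y - H %*% m_p))
    P_k <- (diag(6) - K %*% H) %*% P_p
    expect_equal(b$mean, m_k, tolerance = 1e-8)
    expect_equal(b$cov, (P_k + t(P_k)) / 2, tolerance = 1e-8)
  }
})

test_that("with untuned cells the mixture degrades to the prior prediction", {
  km <- kinematic_model(log(c(5, 6, 7)), matrix(0, 3, 4))
  set.seed(17)
  sp <- matrix(rbinom(3 * 120, 1, 0.03), 3)
  out <- fc_p_ppf_decode(sp, c(0.1, 0), default_grid, default_sys, km)
  # each active filter follows its own noiseless prior; weights stay uniform,
  # so the combined estimate is the weight-averaged prior path
  prior_means <- sapply(default_grid$bins, function(Tb) {
    g <- solve_lqg(default_sys, cost_spec(c(0.1, 0), Tb))
    b <- gaussian_belief()
    for (t in 1:120) b <- ppf_predict(b, default_sys, gain_at(g, t), g$x_star)
    b$mean[1]
  })
  active <- which(default_grid$bins >= 120)
  expect_equal(out$states[120, 1], mean(prior_means[active]),
               tolerance = 1e-6)
  expect_equal(unname(out$weights[120, active]),
               rep(1 / length(active), length(active)), tolerance = 1e-9)
})
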