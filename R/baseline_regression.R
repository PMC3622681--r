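#' Sliding-window firing rates
#'
#' Converts a binary spike train into firing rates computed every `step_ms`
#' in trailing (causal) windows of `window_ms`: the rate at bin `t` uses
#' spikes in bins `t - w + 1 .. t` only.  Leading bins, where the full
#' window extends before the trial start, are normalized by the truncated
#' window duration.
#'
#' @param spikes Integer matrix, neurons x bins (bin width `step_ms`).
#' @param window_ms Window length, ms (multiple of `step_ms`).
#' @param step_ms Bin step, ms.
#' @return Numeric matrix, bins x neurons, in spikes/s.
#' @export
sliding_rates <- function(spikes, window_ms = 100, step_ms = 5) {
  spikes <- as.matrix(spikes)
  w <- window_ms / step_ms
  if (abs(w - round(w)) > 1e-9) stop("window must be a multiple of the step",
                                     call. = FALSE)
  w <- as.integer(round(w))
  n_bins <- ncol(spikes)
  cs <- apply(spikes, 1, cumsum)                    # bins x neurons
  if (n_bins == 1L) cs <- matrix(cs, nrow = 1L)
  counts <- cs
  if (n_bins > w) {
    lag <- rbind(matrix(0, w, ncol(cs)),
                 cs[seq_len(n_bins - w), , drop = FALSE])
    counts <- cs - lag
  }
  eff_w <- pmin(seq_len(n_bins), w) * step_ms / 1000
  sweep(counts, 1, eff_w, "/")
}

#' Shuffle firing rates across time and trials
#'
#' Independently permutes each neuron's rate values across all time bins
#' (rows), preserving the per-neuron multiset of values and hence the mean
#' rate.  This is the chance-level control for regression decoding: rates
#' carry no kinematic information after shuffling.  Uses the current RNG
#' state, so a fixed seed reproduces the permutation.
#'
#' @param R Numeric matrix, time bins (pooled across trials) x neurons.
#' @return Matrix of the same shape with shuffled columns.
#' @export
shuffle_rates <- function(R) {
  R <- as.matrix(R)
  for (j in seq_len(ncol(R))) R[, j] <- R[sample.int(nrow(R)), j]
  R
}

# lagged standardized design: row t = (z_t, z_{t-1}, ..., z_{t-K+1}),
# zero-padded (i.e., at the training mean) before the trial start
lag_design <- function(rates, K, mu, sd) {
  Z <- sweep(sweep(rates, 2, mu), 2, sd, "/")
  n <- nrow(Z); p <- ncol(Z)
  out <- matrix(0, n, p * K)
  for (l in seq_len(K) - 1L) {
    if (l + 1L > n) break
    rows <- (l + 1L):n
    out[rows, (l * p + 1L):((l + 1L) * p)] <- Z[rows - l, , drop = FALSE]
  }
  out
}

#' Ridge regression of position on rate history
#'
#' Solves `f = (R'R + delta I)^{-1} R' q` for each position dimension, with
#' `q` mean-subtracted.  `delta = 0` gives ordinary least squares.
#'
#' @param R Design matrix (time samples x coefficients), already
#'   standardized/lagged.
#' @param q Matrix of positions (time samples x 2), not yet mean-subtracted.
#' @param delta Regularization parameter, >= 0.
#' @return Object of class `bmi_ridge_fit`: `coefficients` (p x 2), `delta`,
#'   `q_mean`, `train_mse`.
#' @export
fit_ridge <- function(R, q, delta) {
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  R <- as.matrix(R); q <- as.matrix(q)
  q_mean <- colMeans(q)
  qc <- sweep(q, 2, q_mean)
  G <- crossprod(R) + diag(delta, ncol(R))
  f <- solve(G, crossprod(R, qc))
  pred <- R %*% f
  structure(list(coefficients = f, delta = delta, q_mean = q_mean,
                 train_mse = mean((qc - pred)^2)),
            class = "bmi_ridge_fit")
}

predict_ridge_design <- function(fit, R) {
  sweep(as.matrix(R) %*% fit$coefficients, 2, fit$q_mean, "+")
}

#' Ridge decoder with history-length and regularizer selection
#'
#' Fits the ridge-regression position decoder on sliding-window firing
#' rates, selecting the history length (default 200/400/600/800 ms) and the
#' regularization parameter (logarithmic grid scaled by the size of `R'R`)
#' that minimize leave-one-trial-out cross-validated mean-square error.
#' Standardization statistics and the position mean are frozen from the
#' training session and reused at prediction time (also inside the
#' cross-validation folds, which keeps the fold Gram matrices reusable;
#' with tens of trials per session the session- and fold-level statistics
#' are practically identical).
#'
#' The leave-one-out sweep holds one Gram matrix per trial in memory
#' (`(neurons x lags)^2` doubles each); with long histories keep the
#' training set to a few tens of trials.
#'
#' @param rate_trials List of per-trial rate matrices (bins x neurons), e.g.
#'   from [sliding_rates()] on movement-epoch spikes.
#' @param pos_trials List of per-trial position matrices (bins x 2), aligned
#'   with `rate_trials`.
#' @param histories_ms Candidate history lengths, ms.
#' @param delta_grid Candidate regularizers; default `10^seq(-4, 4)` scaled
#'   by `mean(diag(R'R))` of the full design.
#' @param step_ms Bin step, ms.
#' @return Object of class `bmi_ridge_decoder`: the selected
#'   `bmi_ridge_fit` plus `history_ms`, `K` (lags), `mu`/`sd`
#'   (standardization), `cv_mse` (history x delta matrix) and the selected
#'   `cv_mse_min`.
#' @export
select_ridge_model <- function(rate_trials, pos_trials,
                               histories_ms = c(200, 400, 600, 800),
                               delta_grid = NULL, step_ms = 5) {
  n_trials <- length(rate_trials)
  if (n_trials < 3L) stop("need at least 3 trials for cross-validation",
                          call. = FALSE)
  if (length(pos_trials) != n_trials)
    stop("rate and position trial lists must align", call. = FALSE)
  Ks <- as.integer(round(histories_ms / step_ms))
  if (any(Ks < 1L)) stop("degenerate history grid", call. = FALSE)
  all_rates <- do.call(rbind, rate_trials)
  if (is.null(delta_grid)) {
    p_max <- ncol(all_rates) * max(Ks)
    scale <- mean(colSums(scale(all_rates, scale = FALSE)^2)) * max(Ks)
    delta_grid <- 10^seq(-4, 4, by = 1) * scale / p_max
  }
  mu <- colMeans(all_rates)
  sd <- apply(all_rates, 2, stats::sd); sd[sd < 1e-12] <- 1
  q_all <- do.call(rbind, pos_trials)
  q_mean <- colMeans(q_all)
  cv <- matrix(NA_real_, length(Ks), length(delta_grid),
               dimnames = list(paste0(histories_ms, "ms"), NULL))
  for (h in seq_along(Ks)) {
    K <- Ks[h]
    X_i <- lapply(rate_trials, lag_design, K = K, mu = mu, sd = sd)
    qc_i <- lapply(pos_trials, function(q) sweep(as.matrix(q), 2, q_mean))
    G_i <- lapply(X_i, crossprod)
    Xq_i <- mapply(crossprod, X_i, qc_i, SIMPLIFY = FALSE)
    G_all <- Reduce(`+`, G_i)
    Xq_all <- Reduce(`+`, Xq_i)
    err <- matrix(0, n_trials, length(delta_grid))
    for (i in seq_len(n_trials)) {
      G <- G_all - G_i[[i]]
      Xq <- Xq_all - Xq_i[[i]]
      for (d in seq_along(delta_grid)) {
        f <- solve(G + diag(delta_grid[d], ncol(G)), Xq)
        pred <- X_i[[i]] %*% f
        err[i, d] <- mean((qc_i[[i]] - pred)^2)
      }
    }
    cv[h, ] <- colMeans(err)
  }
  best <- arrayInd(which.min(cv), dim(cv))
  K <- Ks[best[1]]
  X <- do.call(rbind, lapply(rate_trials, lag_design, K = K, mu = mu, sd = sd))
  fit <- fit_ridge(X, q_all, delta_grid[best[2]])
  structure(list(fit = fit, history_ms = histories_ms[best[1]], K = K,
                 mu = mu, sd = sd, delta = delta_grid[best[2]],
                 delta_grid = delta_grid, cv_mse = cv,
                 cv_mse_min = min(cv)),
            class = "bmi_ridge_decoder")
}

#' Predict positions for one trial with a fitted ridge decoder
#'
#' @param decoder A `bmi_ridge_decoder` from [select_ridge_model()].
#' @param rates Rate matrix for the trial (bins x neurons), same neuron
#'   order as in training.
#' @return Matrix bins x 2 of estimated positions.
#' @export
predict_ridge <- function(decoder, rates) {
  X <- lag_design(as.matrix(rates), decoder$K, decoder$mu, decoder$sd)
  predict_ridge_design(decoder$fit, X)
}
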