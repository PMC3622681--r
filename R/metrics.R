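#' Acquisition accuracy of a set of trial outcomes
#'
#' Percentage of trials on which the task is completed successfully (the
#' cued target is the first disk touched, within the time-out).
#'
#' @param outcomes List of `bmi_trial_outcome`s (or `bmi_trial_record`s
#'   carrying outcomes).
#' @return Percent in `[0, 100]`.
#' @export
acquisition_accuracy <- function(outcomes) {
  outcomes <- extract_outcomes(outcomes)
  if (length(outcomes) == 0L) stop("no outcomes supplied", call. = FALSE)
  100 * mean(vapply(outcomes, function(o) isTRUE(o$success), logical(1)))
}

extract_outcomes <- function(x) {
  lapply(x, function(el) {
    if (inherits(el, "bmi_trial_record")) el$outcome else el
  })
}

#' Root-mean-square trajectory error
#'
#' Square root of the mean (over bins) squared Euclidean position error
#' between an estimated and a true trajectory.
#'
#' @param est,truth Matrices bins x 2 of positions, aligned bin for bin.
#' @return RMS error in workspace units.
#' @export
rms_error <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!all(dim(est) == dim(truth)))
    stop("trajectories must have matching dimensions", call. = FALSE)
  sqrt(mean(rowSums((est - truth)^2)))
}

#' Decoding signal-to-noise ratio
#'
#' Ratio of the variance of the true position signal to the mean-squared
#' estimation error, computed per dimension and averaged.  A perfect
#' estimate returns `Inf`; an estimate pinned at the signal mean returns 1.
#'
#' @param est,truth Matrices bins x 2 of positions.
#' @return Non-negative ratio (possibly `Inf`).
#' @export
snr <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!all(dim(est) == dim(truth)))
    stop("trajectories must have matching dimensions", call. = FALSE)
  n <- nrow(truth)
  per_dim <- vapply(seq_len(ncol(truth)), function(j) {
    v <- mean((truth[, j] - mean(truth[, j]))^2)   # population variance
    mse <- mean((est[, j] - truth[, j])^2)
    if (mse == 0) Inf else v / mse
  }, 0)
  mean(per_dim)
}

#' Roughness coefficient of a trajectory
#'
#' Normalized first-difference energy,
#' `sum_t ||x_t - x_{t-1}||^2 / sum_t ||x_t - x_bar||^2`, over the position
#' components — smaller for smoother trajectories.  The vector form uses
#' Euclidean norms, making the coefficient invariant to rigid translation
#' and rotation.
#'
#' @param traj Matrix bins x 2 of positions (>= 3 bins).
#' @return Non-negative coefficient; `NaN` for a constant trajectory.
#' @export
roughness <- function(traj) {
  traj <- as.matrix(traj)
  if (nrow(traj) < 3L) stop("need at least 3 bins", call. = FALSE)
  num <- sum(rowSums(diff(traj)^2))
  ctr <- sweep(traj, 2, colMeans(traj))
  den <- sum(rowSums(ctr^2))
  if (den == 0) return(NaN)
  num / den
}

#' Correction rate between two decoders on the same trials
#'
#' Percentage of the trials that decoder A got wrong which decoder B got
#' right.  Not symmetric in its arguments.
#'
#' @param outcomes_a,outcomes_b Outcome lists over the same trial set.
#' @return Percent, or `NaN` when A has no incorrect trials.
#' @export
correction_rate <- function(outcomes_a, outcomes_b) {
  a <- vapply(extract_outcomes(outcomes_a), function(o) isTRUE(o$success),
              logical(1))
  b <- vapply(extract_outcomes(outcomes_b), function(o) isTRUE(o$success),
              logical(1))
  if (length(a) != length(b)) stop("outcome lists must align", call. = FALSE)
  if (all(a)) return(NaN)
  100 * sum(!a & b) / sum(!a)
}

#' Summarize a session
#'
#' @param records List of `bmi_trial_record`s with outcomes.
#' @return List with `n_trials`, `accuracy_pct`, `median_acquisition_s`,
#'   mean `roughness` of the movement paths, and the per-trial outcome
#'   table (data frame).
#' @export
summarize_session <- function(records) {
  outs <- lapply(records, function(r) r$outcome)
  tab <- data.frame(
    trial = seq_along(records),
    cued = vapply(records, function(r) r$cued_target, 0L),
    success = vapply(outs, function(o) isTRUE(o$success), logical(1)),
    cause = vapply(outs, function(o) o$cause, ""),
    first_hit = vapply(outs, function(o)
      if (is.na(o$first_target_hit)) NA_integer_ else o$first_target_hit, 0L),
    acquisition_ms = vapply(outs, function(o) o$acquisition_time_ms, 0)
  )
  rough <- vapply(records, function(r) {
    mov <- tryCatch(movement_epoch(r), error = function(e) NULL)
    if (is.null(mov) || nrow(mov$kinematics) < 3L) return(NA_real_)
    roughness(mov$kinematics[, 1:2, drop = FALSE])
  }, 0)
  list(n_trials = length(records),
       accuracy_pct = acquisition_accuracy(outs),
       median_acquisition_s =
         stats::median(tab$acquisition_ms, na.rm = TRUE) / 1000,
       roughness = mean(rough, na.rm = TRUE),
       outcomes = tab)
}
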