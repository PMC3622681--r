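#' Center-out task configuration
#'
#' Builds the configuration of the instructed-delay center-out task: target
#' geometry, epoch timing, and the spike binning width.  Defaults follow the
#' standard four-target layout with a 500 ms central hold, a 1000 ms
#' instruction (delay) epoch of which the last 800 ms are used for target
#' decoding, a 3 s movement time-out, and 5 ms spike bins.
#'
#' The workspace is dimensionless; the default reach distance of 0.1 puts the
#' plant parameters (SI units) on a ~10 cm reach scale.
#'
#' @param n_targets Number of peripheral targets (>= 2).
#' @param target_angles Angles of the target centers in radians.  Defaults to
#'   `n_targets` equally spaced angles starting at 0 (cardinal directions for
#'   four targets).
#' @param target_distance Distance from the center to each target center.
#' @param target_radius Radius of each circular target; must be smaller than
#'   `target_distance`.
#' @param hold_ms Central hold duration before target onset, ms.
#' @param instruct_ms Instruction (delay) epoch between target onset and the
#'   go cue, ms.
#' @param delay_window_ms Portion of the delay epoch used for target
#'   decoding, ms (the window ends at the go cue).
#' @param discard_ms Time after target onset excluded from target decoding,
#'   ms (visual latency to premotor cortex).
#' @param timeout_ms Maximum movement time after the go cue, ms.
#' @param bin_ms Spike bin width, ms; must divide every epoch duration.
#' @return An object of class `bmi_task_config`.
#' @examples
#' cfg <- make_center_out_config()
#' target_centers(cfg)
#' @export
make_center_out_config <- function(n_targets = 4L,
                                   target_angles = NULL,
                                   target_distance = 0.1,
                                   target_radius = 0.025,
                                   hold_ms = 500,
                                   instruct_ms = 1000,
                                   delay_window_ms = 800,
                                   discard_ms = 200,
                                   timeout_ms = 3000,
                                   bin_ms = 5) {
  n_targets <- as.integer(n_targets)
  if (is.na(n_targets) || n_targets < 2L)
    stop("n_targets must be an integer >= 2", call. = FALSE)
  if (is.null(target_angles))
    target_angles <- 2 * pi * (seq_len(n_targets) - 1L) / n_targets
  if (length(target_angles) != n_targets)
    stop("target_angles must have length n_targets", call. = FALSE)
  if (!(target_distance > 0) || !(target_radius > 0))
    stop("target_distance and target_radius must be positive", call. = FALSE)
  if (target_radius >= target_distance)
    stop("target_radius must be smaller than target_distance", call. = FALSE)
  durs <- c(hold_ms = hold_ms, instruct_ms = instruct_ms,
            delay_window_ms = delay_window_ms, discard_ms = discard_ms,
            timeout_ms = timeout_ms)
  if (any(durs < 0) || bin_ms <= 0)
    stop("epoch durations must be non-negative and bin_ms positive", call. = FALSE)
  if (delay_window_ms + discard_ms > instruct_ms)
    stop("delay_window_ms + discard_ms must not exceed instruct_ms", call. = FALSE)
  off <- vapply(durs, function(d) abs(d / bin_ms - round(d / bin_ms)), 0)
  if (any(off > 1e-9))
    stop("bin_ms must divide all epoch durations", call. = FALSE)
  structure(list(
    n_targets = n_targets,
    target_angles = as.numeric(target_angles),
    target_distance = target_distance,
    target_radius = target_radius,
    hold_ms = hold_ms,
    instruct_ms = instruct_ms,
    delay_window_ms = delay_window_ms,
    discard_ms = discard_ms,
    timeout_ms = timeout_ms,
    bin_ms = bin_ms
  ), class = "bmi_task_config")
}

#' Target center coordinates
#'
#' @param config A `bmi_task_config`.
#' @return An `n_targets` x 2 matrix of target center positions.
#' @export
target_centers <- function(config) {
  stopifnot(inherits(config, "bmi_task_config"))
  cbind(x = config$target_distance * cos(config$target_angles),
        y = config$target_distance * sin(config$target_angles))
}

#' Number of 5 ms bins in each task epoch
#'
#' @param config A `bmi_task_config`.
#' @return Named list with `instruct`, `decode`, `discard` and `timeout` bin
#'   counts.
#' @keywords internal
epoch_bins <- function(config) {
  list(instruct = as.integer(round(config$instruct_ms / config$bin_ms)),
       decode = as.integer(round(config$delay_window_ms / config$bin_ms)),
       discard = as.integer(round(config$discard_ms / config$bin_ms)),
       timeout = as.integer(round(config$timeout_ms / config$bin_ms)))
}

#' Score a movement path against the center-out task rules
#'
#' Walks the cursor path bin by bin from the go cue.  The first bin at which
#' the cursor lies within (closed disk, `<=` radius) any target ends the
#' trial: the trial succeeds if and only if that target is the cued one and
#' the entry time does not exceed the time-out.  Touching any other target
#' first aborts the trial (`incorrect_touch`); never entering a disk within
#' the time-out is a `timeout`.
#'
#' @param positions Numeric matrix (bins x 2) of cursor positions sampled
#'   every `bin_ms` starting one bin after the go cue.
#' @param config A `bmi_task_config`.
#' @param cued Cued target id (1-based).
#' @return An object of class `bmi_trial_outcome`: list with `success`,
#'   `first_target_hit` (id or `NA`), `cause` (one of `"correct"`,
#'   `"incorrect_touch"`, `"timeout"`), and `acquisition_time_ms` (`NA` on
#'   timeout).
#' @export
score_trial <- function(positions, config, cued) {
  stopifnot(inherits(config, "bmi_task_config"))
  positions <- as.matrix(positions)
  if (nrow(positions) == 0L) stop("empty movement path", call. = FALSE)
  if (ncol(positions) != 2L) stop("positions must have two columns", call. = FALSE)
  cued <- as.integer(cued)
  if (cued < 1L || cued > config$n_targets) stop("invalid cued target id", call. = FALSE)
  centers <- target_centers(config)
  n_bins <- min(nrow(positions), epoch_bins(config)$timeout)
  r2 <- config$target_radius^2
  for (t in seq_len(n_bins)) {
    d2 <- (centers[, 1] - positions[t, 1])^2 + (centers[, 2] - positions[t, 2])^2
    hit <- which(d2 <= r2)
    if (length(hit)) {
      hit <- hit[which.min(d2[hit])]
      return(structure(list(
        success = identical(hit, cued) || hit == cued,
        first_target_hit = as.integer(hit),
        cause = if (hit == cued) "correct" else "incorrect_touch",
        acquisition_time_ms = t * config$bin_ms
      ), class = "bmi_trial_outcome"))
    }
  }
  structure(list(success = FALSE, first_target_hit = NA_integer_,
                 cause = "timeout", acquisition_time_ms = NA_real_),
            class = "bmi_trial_outcome")
}

#' Construct a trial record
#'
#' Bundles the spiking activity, kinematics and metadata of one trial.  Bins
#' run from target onset; the instruction epoch occupies the first
#' `instruct_ms / bin_ms` bins and movement bins follow the go cue.
#'
#' @param cued_target Cued target id.
#' @param spikes Integer matrix, neurons x bins, of binary spike indicators.
#' @param kinematics Numeric matrix, bins x 6, columns
#'   `(p_x, p_y, v_x, v_y, f_x, f_y)`.
#' @param epoch_marks Integer vector `c(target_onset, go_cue)` of bin indices:
#'   `target_onset` is the first instruction bin, `go_cue` the last (movement
#'   starts at `go_cue + 1`).
#' @param outcome Optional `bmi_trial_outcome`.
#' @return An object of class `bmi_trial_record`.
#' @export
trial_record <- function(cued_target, spikes, kinematics, epoch_marks,
                         outcome = NULL) {
  spikes <- as.matrix(spikes)
  kinematics <- as.matrix(kinematics)
  if (ncol(spikes) != nrow(kinematics))
    stop("spikes and kinematics must share the bin count", call. = FALSE)
  if (ncol(kinematics) != 6L)
    stop("kinematics must have 6 columns (p, v, f in 2-D)", call. = FALSE)
  epoch_marks <- as.integer(epoch_marks)
  if (length(epoch_marks) != 2L || diff(epoch_marks) <= 0L)
    stop("epoch_marks must be two strictly increasing bin indices", call. = FALSE)
  structure(list(cued_target = as.integer(cued_target),
                 spikes = matrix(as.integer(spikes), nrow(spikes), ncol(spikes)),
                 kinematics = kinematics, epoch_marks = epoch_marks,
                 outcome = outcome),
            class = "bmi_trial_record")
}

#' Extract the delay-period decoding window of a trial
#'
#' Returns the spike bins covering the last `delay_window_ms` before the go
#' cue (the first `discard_ms` after target onset never enter this window).
#'
#' @param record A `bmi_trial_record`.
#' @param config A `bmi_task_config`.
#' @return Integer matrix neurons x decode-window bins.
#' @export
delay_window_spikes <- function(record, config) {
  eb <- epoch_bins(config)
  go <- record$epoch_marks[2]
  idx <- (go - eb$decode + 1L):go
  record$spikes[, idx, drop = FALSE]
}

#' Extract movement-epoch spikes and kinematics of a trial
#'
#' @param record A `bmi_trial_record`.
#' @return List with `spikes` (neurons x movement bins) and `kinematics`
#'   (movement bins x 6).
#' @export
movement_epoch <- function(record) {
  go <- record$epoch_marks[2]
  n <- ncol(record$spikes)
  if (go >= n) stop("trial has no movement bins", call. = FALSE)
  idx <- (go + 1L):n
  list(spikes = record$spikes[, idx, drop = FALSE],
       kinematics = record$kinematics[idx, , drop = FALSE])
}

# ---- session I/O ---------------------------------------------------------
# A session is a directory of plain-text files: meta.json (config echo and
# per-trial metadata), spikes.csv (sparse long format: trial, neuron, bin of
# each spike) and kinematics.csv (long format: trial, bin, p/v/f columns).

#' Write a session to disk
#'
#' Serializes trial records losslessly to a directory of plain-text files:
#' `meta.json` (trial metadata and outcomes), `spikes.csv` (one row per spike
#' event: trial, neuron, bin) and `kinematics.csv` (one row per bin).  Writing
#' the same records twice produces byte-identical files.
#'
#' @param records List of `bmi_trial_record`s.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(records, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  meta <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    out <- r$outcome
    list(trial = i, cued_target = r$cued_target,
         n_neurons = nrow(r$spikes), n_bins = ncol(r$spikes),
         epoch_marks = r$epoch_marks,
         outcome = if (is.null(out)) NULL else
           list(success = out$success, first_target_hit = out$first_target_hit,
                cause = out$cause, acquisition_time_ms = out$acquisition_time_ms))
  })
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null",
                       pretty = TRUE)
  sp <- do.call(rbind, lapply(seq_along(records), function(i) {
    w <- which(records[[i]]$spikes == 1L, arr.ind = TRUE)
    if (nrow(w) == 0L) return(NULL)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    data.frame(trial = i, neuron = w[, 1], bin = w[, 2])
  }))
  if (is.null(sp)) sp <- data.frame(trial = integer(), neuron = integer(),
                                    bin = integer())
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  kin <- do.call(rbind, lapply(seq_along(records), function(i) {
    k <- records[[i]]$kinematics
    data.frame(trial = i, bin = seq_len(nrow(k)),
               p_x = k[, 1], p_y = k[, 2], v_x = k[, 3], v_y = k[, 4],
               f_x = k[, 5], f_y = k[, 6])
  }))
  if (is.null(kin)) kin <- data.frame(trial = integer(), bin = integer(),
                                      p_x = numeric(), p_y = numeric(),
                                      v_x = numeric(), v_y = numeric(),
                                      f_x = numeric(), f_y = numeric())
  utils::write.csv(format_numeric_df(kin), file.path(path, "kinematics.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed-format numeric printing keeps re-serialization byte-identical
format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.12g", df[[j]])
  }
  df
}

#' Read a session from disk
#'
#' @param path Session directory written by [write_session()].
#' @return List of `bmi_trial_record`s.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a session directory: ", path, call. = FALSE)
  meta <- jsonlite::read_json(mf)
  sp <- utils::read.csv(file.path(path, "spikes.csv"))
  kin <- utils::read.csv(file.path(path, "kinematics.csv"))
  lapply(meta, function(m) {
    i <- m$trial
    spikes <- matrix(0L, m$n_neurons, m$n_bins)
    rows <- sp[sp$trial == i, , drop = FALSE]
    if (nrow(rows)) {
      bad <- rows$neuron > m$n_neurons | rows$bin > m$n_bins
      if (any(bad)) stop("corrupt spike entries in trial ", i, call. = FALSE)
      spikes[cbind(rows$neuron, rows$bin)] <- 1L
    }
    kr <- kin[kin$trial == i, , drop = FALSE]
    if (nrow(kr) != m$n_bins) stop("corrupt kinematics for trial ", i, call. = FALSE)
    kr <- kr[order(kr$bin), , drop = FALSE]
    kmat <- as.matrix(kr[, c("p_x", "p_y", "v_x", "v_y", "f_x", "f_y")])
    dimnames(kmat) <- NULL
    out <- NULL
    if (!is.null(m$outcome)) {
      o <- m$outcome
      out <- structure(list(
        success = isTRUE(o$success),
        first_target_hit = if (is.null(o$first_target_hit)) NA_integer_ else
          as.integer(o$first_target_hit),
        cause = o$cause,
        acquisition_time_ms = if (is.null(o$acquisition_time_ms)) NA_real_ else
          as.numeric(o$acquisition_time_ms)
      ), class = "bmi_trial_outcome")
    }
    trial_record(m$cued_target, spikes, kmat,
                 unlist(m$epoch_marks), out)
  })
}
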