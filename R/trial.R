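#' Subject metadata
#'
#' @param subject_id Subject identifier (string).
#' @param mass Body mass in kg; must be positive.
#' @param leg_length Optional leg length in m.
#' @return A `subject_meta` list.
#' @export
subject_meta <- function(subject_id, mass, leg_length = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    abort("subject_id must be a non-empty string")
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    abort("mass must be a positive finite number (kg)")
  structure(list(subject_id = subject_id, mass = as.numeric(mass),
                 leg_length = if (is.null(leg_length)) NULL else as.numeric(leg_length)),
            class = "subject_meta")
}

#' Condition metadata
#'
#' Describes one walking condition: treadmill incline grade (fraction, e.g.
#' 0.10 for a 10% grade), carried load as a fraction of bodyweight, net
#' exoskeleton assistance work per gait cycle (J, 0 if unassisted), and a flag
#' marking the subject's normal (baseline) walking trial used for EMG
#' normalization.
#'
#' @param condition_id Condition identifier (string).
#' @param incline_grade Incline as a fraction (0.05 = 5% grade).
#' @param load_fraction Carried load as a fraction of bodyweight; `>= 0`.
#' @param assistance_work Assistance work per gait cycle in J.
#' @param is_baseline_normal_walk `TRUE` for the normal walking trial.
#' @return A `condition_meta` list.
#' @export
condition_meta <- function(condition_id, incline_grade = 0, load_fraction = 0,
                           assistance_work = 0, is_baseline_normal_walk = FALSE) {
  if (!is.character(condition_id) || length(condition_id) != 1L || !nzchar(condition_id))
    abort("condition_id must be a non-empty string")
  if (!is.numeric(load_fraction) || load_fraction < 0)
    abort("load_fraction must be >= 0")
  structure(list(condition_id = condition_id,
                 incline_grade = as.numeric(incline_grade),
                 load_fraction = as.numeric(load_fraction),
                 assistance_work = as.numeric(assistance_work),
                 is_baseline_normal_walk = isTRUE(is_baseline_normal_walk)),
            class = "condition_meta")
}

#' One subject-by-condition recording
#'
#' Bundles the synchronized signal channels (all sampled at the same rate and
#' of equal length), the breath-by-breath gas-exchange series, and subject /
#' condition metadata.  At least one channel must be the right-foot vertical
#' ground reaction force (`"grf_r_z"`), which anchors gait-cycle segmentation.
#'
#' @param subject A [subject_meta()].
#' @param condition A [condition_meta()].
#' @param signals A data frame / tibble, one numeric column per channel;
#'   column names follow the `"<kind>_<side>_<axis|muscle>"` convention.
#' @param breaths A tibble with columns `time` (s, strictly increasing),
#'   `vo2`, `vco2` (L/min, non-negative).
#' @param sampling_rate Sampling rate of all channels, Hz.
#' @return A `trial_recording` object.
#' @export
trial_recording <- function(subject, condition, signals, breaths, sampling_rate) {
  if (!inherits(subject, "subject_meta")) abort("subject must be a subject_meta")
  if (!inherits(condition, "condition_meta")) abort("condition must be a condition_meta")
  signals <- as_tibble(as.data.frame(signals))
  breaths <- as_tibble(as.data.frame(breaths))
  trial <- structure(list(subject = subject, condition = condition,
                          signals = signals, breaths = breaths,
                          sampling_rate = as.numeric(sampling_rate)),
                     class = "trial_recording")
  validate_trial(trial)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> subject %s, condition %s\n",
              x$subject$subject_id, x$condition$condition_id))
  cat(sprintf("  %d channels x %d samples @ %g Hz; %d breaths; mass %.1f kg\n",
              ncol(x$signals), nrow(x$signals), x$sampling_rate,
              nrow(x$breaths), x$subject$mass))
  invisible(x)
}

#' Validate a trial recording
#'
#' Checks all structural invariants: positive sampling rate, finite samples of
#' equal length across channels, well-formed channel names including a
#' right-foot vertical GRF, non-negative gas volumes and strictly increasing
#' breath times.
#'
#' @param trial A `trial_recording`.
#' @return The trial, invisibly unchanged, or an error naming the failing field.
#' @export
validate_trial <- function(trial) {
  if (!inherits(trial, "trial_recording")) abort("not a trial_recording")
  if (!is.finite(trial$sampling_rate) || trial$sampling_rate <= 0)
    abort("sampling_rate must be positive")
  sig <- trial$signals
  if (ncol(sig) < 1L || nrow(sig) < 1L)
    abort("signals must have at least one channel and one sample")
  for (nm in names(sig)) {
    if (!is.numeric(sig[[nm]]))
      abort(paste0("signals column '", nm, "' is not numeric"))
    if (!all(is.finite(sig[[nm]])))
      abort(paste0("signals column '", nm, "' contains non-finite samples"))
  }
  parse_channel_names(names(sig))     # errors on malformed names
  right_vertical_grf_name(names(sig)) # errors if absent
  br <- trial$breaths
  if (!all(c("time", "vo2", "vco2") %in% names(br)))
    abort("breaths must have columns time, vo2, vco2")
  if (nrow(br) > 0L) {
    if (any(br$vo2 < 0) || any(br$vco2 < 0))
      abort("breaths: vo2/vco2 must be non-negative")
    if (any(diff(br$time) <= 0))
      abort("breaths: time must be strictly increasing")
  }
  invisible(trial)
}

#' Channel names of a trial
#' @param trial A `trial_recording`.
#' @return Character vector of channel names in stored order.
#' @export
trial_channels <- function(trial) names(trial$signals)

#' Trial duration in seconds
#' @param trial A `trial_recording`.
#' @return Duration of the signal channels in s.
#' @export
trial_duration <- function(trial) nrow(trial$signals) / trial$sampling_rate
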