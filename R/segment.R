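#' Detect heel strikes on a vertical GRF channel
#'
#' A heel strike is an upward threshold crossing: sample `i` with
#' `x[i-1] < threshold <= x[i]`.  Crossings closer than `refractory` seconds
#' to the previous accepted strike are discarded, which suppresses chatter
#' around the threshold within one stance phase.
#'
#' @param x Vertical ground reaction force samples, N (right foot for
#'   gait-cycle segmentation).
#' @param sampling_rate Sampling rate, Hz.
#' @param threshold Crossing threshold, N (default 30: far above the filtered
#'   noise floor, far below bodyweight).
#' @param refractory Minimum separation between strikes, s (default 0.5:
#'   shorter than any walking stride).
#' @return Integer sample indices of accepted strikes, ascending; possibly
#'   empty.
#' @export
detect_heel_strikes <- function(x, sampling_rate, threshold = 30,
                                refractory = 0.5) {
  if (threshold <= 0) abort("threshold must be positive")
  n <- length(x)
  if (n < 2L) return(integer(0))
  cross <- which(x[-1L] >= threshold & x[-n] < threshold) + 1L
  if (length(cross) == 0L) return(integer(0))
  min_gap <- refractory * sampling_rate
  keep <- cross[1L]
  last <- cross[1L]
  for (i in cross[-1L]) {
    if (i - last >= min_gap) {
      keep <- c(keep, i)
      last <- i
    }
  }
  keep
}

#' Slice a trial into gait cycles
#'
#' One segment per consecutive pair of right heel strikes, half-open
#' `[start, end)`; every channel is sliced identically, so concatenating the
#' segments reproduces the span between the first and last strike.
#'
#' @param trial A `trial_recording` (typically already conditioned by
#'   [preprocess_trial()]).
#' @param heel_strikes Integer strike indices from [detect_heel_strikes()].
#' @return A tibble with one row per cycle: `subject_id`, `condition_id`,
#'   `cycle`, `start`, `end`, and a list-column `signals` holding each
#'   cycle's channel slices as a tibble.  Empty (with a warning) if fewer
#'   than two strikes.
#' @export
segment_gait_cycles <- function(trial, heel_strikes) {
  empty <- tibble(subject_id = character(), condition_id = character(),
                  cycle = integer(), start = integer(), end = integer(),
                  signals = list())
  if (length(heel_strikes) < 2L) {
    warn(sprintf("Trial %s/%s: fewer than 2 heel strikes; no gait cycles",
                 trial$subject$subject_id, trial$condition$condition_id))
    return(empty)
  }
  starts <- heel_strikes[-length(heel_strikes)]
  ends <- heel_strikes[-1L]
  tibble(
    subject_id = trial$subject$subject_id,
    condition_id = trial$condition$condition_id,
    cycle = seq_along(starts),
    start = as.integer(starts),
    end = as.integer(ends),
    signals = map2(starts, ends, function(s, e) trial$signals[s:(e - 1L), ])
  )
}

#' Slice a trial into fixed-duration block-averaged windows
#'
#' Consecutive non-overlapping spans of `window_s` seconds; within each span
#' every channel is averaged over consecutive blocks of `block` samples, so a
#' 4 s span at 2000 Hz becomes 250 time steps.  A trailing partial span is
#' discarded.
#'
#' @param trial A `trial_recording`.
#' @param window_s Window duration, s (default 4).
#' @param block Samples averaged per output step (default 32).
#' @return A tibble with one row per window: `subject_id`, `condition_id`,
#'   `window`, and a list-column `matrix` of `(window_s *
#'   sampling_rate / block) x C` matrices (time by channel).  Empty with a
#'   warning if the trial is shorter than one window.
#' @export
segment_fixed_windows <- function(trial, window_s = 4, block = 32) {
  span <- window_s * trial$sampling_rate
  if (abs(span - round(span)) > 1e-9 || round(span) %% block != 0)
    abort("window_s * sampling_rate must be a whole number divisible by block")
  span <- as.integer(round(span))
  n <- nrow(trial$signals)
  n_win <- n %/% span
  if (n_win == 0L) {
    warn(sprintf("Trial %s/%s shorter than one %gs window; no windows",
                 trial$subject$subject_id, trial$condition$condition_id,
                 window_s))
    return(tibble(subject_id = character(), condition_id = character(),
                  window = integer(), matrix = list()))
  }
  steps <- span %/% block
  X <- as.matrix(trial$signals)
  mats <- lapply(seq_len(n_win), function(w) {
    sub <- X[((w - 1L) * span + 1L):(w * span), , drop = FALSE]
    # block-average: mean of each group of `block` consecutive rows
    down <- vapply(seq_len(ncol(sub)), function(j) {
      colMeans(matrix(sub[, j], nrow = block))
    }, numeric(steps))
    colnames(down) <- colnames(X)
    down
  })
  tibble(
    subject_id = trial$subject$subject_id,
    condition_id = trial$condition$condition_id,
    window = seq_len(n_win),
    matrix = mats
  )
}
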