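round_half_up <- function(x) floor(x + 0.5)

#' Bin a gait-cycle segment into a fixed-length feature vector
#'
#' Each channel of the segment is divided into `n_bins` contiguous bins,
#' bin `b` (0-based) covering samples `[round(b*L/n_bins),
#' round((b+1)*L/n_bins))` with half-up rounding, and averaged.  The bins
#' tile the segment exactly and bin widths differ by at most one sample.
#' Channel blocks are concatenated in channel order, giving a vector of
#' length `n_bins * C`.
#'
#' @param signals A tibble/data frame or matrix of one cycle's samples
#'   (rows) by channels (columns).
#' @param n_bins Bins per channel (default 30).
#' @return Named numeric vector of length `n_bins * C`
#'   (`<channel>_b<bin>` names).
#' @export
bin_cycle <- function(signals, n_bins = 30) {
  X <- as.matrix(signals)
  L <- nrow(X)
  if (L < n_bins)
    abort(sprintf("Segment of length %d is shorter than n_bins = %d", L, n_bins))
  bounds <- round_half_up((0:n_bins) * L / n_bins)
  widths <- diff(bounds)
  grp <- rep.int(seq_len(n_bins), widths)
  means <- vapply(seq_len(ncol(X)),
                  function(j) rowsum(X[, j], grp, reorder = TRUE)[, 1] / widths,
                  numeric(n_bins))
  out <- as.numeric(means)
  names(out) <- as.vector(outer(sprintf("b%02d", seq_len(n_bins)),
                                colnames(X), function(b, ch) paste(ch, b, sep = "_")))
  out
}

label_for <- function(labels, subject_id, condition_id) {
  hit <- labels$power_w[labels$subject_id == subject_id &
                          labels$condition_id == condition_id]
  if (length(hit) != 1L)
    abort(sprintf("No (unique) label for subject %s, condition %s",
                  subject_id, condition_id))
  hit
}

normalizers_by_subject <- function(trials) {
  subj <- map_chr(trials, ~ .x$subject$subject_id)
  base <- vapply(trials, function(t)
    isTRUE(t$condition$is_baseline_normal_walk), logical(1))
  out <- list()
  for (s in unique(subj)) {
    idx <- which(subj == s & base)
    if (length(idx) != 1L)
      abort(sprintf(
        "Subject %s must have exactly one baseline normal walking trial (found %d)",
        s, length(idx)))
    out[[s]] <- compute_emg_normalizer(trials[[idx]])
  }
  out
}

#' Assemble the per-gait-cycle feature table
#'
#' Runs the full conditioning pipeline on every trial -- filtering (or
#' raw-rectify when `raw_mode = TRUE`), heel-strike detection on the
#' conditioned right vertical GRF, gait-cycle segmentation, channel-subset
#' selection, and 30-bin averaging -- and labels every cycle of a condition
#' with that condition's steady-state metabolic power.
#'
#' @param trials List of trials.  EMG normalizers are computed per subject
#'   from the subject's baseline normal-walking trial.
#' @param labels Condition labels from [condition_labels()] (columns
#'   `subject_id`, `condition_id`, `power_w`).
#' @param subset Channel subset, see [select_channel_subset()].
#' @param raw_mode Bypass all filtering; EMG rectified only.
#' @param n_bins Bins per channel.
#' @param threshold,refractory Heel-strike detector settings, see
#'   [detect_heel_strikes()].
#' @return A tibble with one row per gait cycle: `subject_id`,
#'   `condition_id`, `cycle`, `mass`, `y` (label, W) and a matrix column `x`
#'   of binned features (`n_bins * C` columns).
#' @export
assemble_features <- function(trials, labels, subset = "all", raw_mode = FALSE,
                              n_bins = 30, threshold = 30, refractory = 0.5) {
  norms <- if (raw_mode) NULL else normalizers_by_subject(trials)
  rows <- list()
  for (t in trials) {
    proc <- preprocess_trial(
      t, normalizers = if (raw_mode) NULL else norms[[t$subject$subject_id]],
      raw_mode = raw_mode)
    grf <- proc$signals[[right_vertical_grf_name(trial_channels(proc))]]
    strikes <- detect_heel_strikes(grf, proc$sampling_rate,
                                   threshold = threshold,
                                   refractory = refractory)
    cyc <- segment_gait_cycles(proc, strikes)
    if (nrow(cyc) == 0L) next
    keep <- select_channel_subset(trial_channels(proc), subset)
    y <- label_for(labels, t$subject$subject_id, t$condition$condition_id)
    feats <- t(vapply(cyc$signals,
                      function(s) bin_cycle(s[, keep, drop = FALSE], n_bins),
                      numeric(n_bins * length(keep))))
    rows[[length(rows) + 1L]] <- tibble(
      subject_id = cyc$subject_id, condition_id = cyc$condition_id,
      cycle = cyc$cycle, mass = t$subject$mass, y = y, x = feats)
  }
  if (length(rows) == 0L) abort("No gait cycles found in any trial")
  out <- bind_rows(rows)
  attr(out, "subset") <- subset
  attr(out, "raw_mode") <- raw_mode
  out
}

#' Assemble the labeled fixed-window table
#'
#' Like [assemble_features()] but segments each trial into non-overlapping
#' block-averaged windows ([segment_fixed_windows()]); the window matrices
#' stay two-dimensional (time by channel) for the recurrent model.
#'
#' @inheritParams assemble_features
#' @param window_s,block See [segment_fixed_windows()].
#' @return A tibble with one row per window: ids, `mass`, `y` and a
#'   list-column `matrix` of time-by-channel matrices.
#' @export
assemble_windows <- function(trials, labels, subset = "all", raw_mode = FALSE,
                             window_s = 4, block = 32) {
  norms <- if (raw_mode) NULL else normalizers_by_subject(trials)
  rows <- list()
  for (t in trials) {
    proc <- preprocess_trial(
      t, normalizers = if (raw_mode) NULL else norms[[t$subject$subject_id]],
      raw_mode = raw_mode)
    keep <- select_channel_subset(trial_channels(proc), subset)
    proc$signals <- proc$signals[, keep, drop = FALSE]
    win <- segment_fixed_windows(proc, window_s = window_s, block = block)
    if (nrow(win) == 0L) next
    win$mass <- t$subject$mass
    win$y <- label_for(labels, t$subject$subject_id, t$condition$condition_id)
    rows[[length(rows) + 1L]] <- win
  }
  if (length(rows) == 0L) {
    warn("No windows found in any trial")
    return(tibble(subject_id = character(), condition_id = character(),
                  window = integer(), matrix = list(),
                  mass = numeric(), y = numeric()))
  }
  out <- bind_rows(rows)
  attr(out, "subset") <- subset
  attr(out, "raw_mode") <- raw_mode
  out
}
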