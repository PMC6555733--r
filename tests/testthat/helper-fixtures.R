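# Shared fixtures, built in code and memoized for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# A small hand-built trial: 2 force channels + 2 EMG channels at 2000 Hz,
# with three rectangular stance pulses at known onsets.
make_pulse_trial <- function(n = 12000, fs = 2000, onsets = c(1000, 3100, 5150),
                             pulse_len = 1200, amp = 800,
                             subject_id = "T01", condition_id = "walk",
                             baseline = TRUE, mass = 70) {
  z <- numeric(n)
  for (s in onsets[onsets <= n]) z[s:min(n, s + pulse_len - 1L)] <- amp
  t <- (seq_len(n) - 1) / fs
  emg1 <- sin(2 * pi * 120 * t) * (z / amp)       # active during stance
  emg2 <- 0.5 * sin(2 * pi * 90 * t + 1) * (z / amp)
  signals <- tibble::tibble(grf_r_z = z, grf_r_y = 0.2 * z,
                            emg_r_soleus = emg1, emg_r_tibant = emg2)
  breaths <- tibble::tibble(time = c(1, 2, 3, 4, 5),
                            vo2 = rep(0.9, 5), vco2 = rep(0.75, 5))
  trial_recording(
    subject_meta(subject_id, mass),
    condition_meta(condition_id, is_baseline_normal_walk = baseline),
    signals, breaths, fs)
}

tiny_assisted <- function() memo("tiny_assisted", function() {
  generate_dataset(synthetic_config("assisted", n_subjects = 2, trial_s = 8,
                                    seed = 42))
})

tiny_incline <- function() memo("tiny_incline", function() {
  generate_dataset(synthetic_config("incline_load", n_subjects = 2, trial_s = 8,
                                    seed = 43))
})

small_planted <- function() memo("small_planted", function() {
  generate_dataset(synthetic_config("assisted", n_subjects = 3, trial_s = 12,
                                    planted_linear = TRUE, seed = 44))
})

# lightweight stand-ins for plan construction (only ids are needed)
fake_trials <- function(subjects, conditions) {
  out <- list()
  for (s in subjects) for (cc in conditions)
    out[[length(out) + 1L]] <- list(subject = list(subject_id = s),
                                    condition = list(condition_id = cc))
  out
}
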