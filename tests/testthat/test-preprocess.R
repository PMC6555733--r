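# analytic Butterworth magnitude oracle: one pass |H(f)| = 1/sqrt(1+(f/fc)^(2n));
# zero-phase application squares it.
butter_zero_phase_gain <- function(f, fc, order = 4) 1 / (1 + (f / fc)^(2 * order))

test_that("GRF low-pass passes DC and the gait band, kills high frequencies", {
  fs <- 2000
  x <- rep(500, 6000)
  expect_equal(filter_grf(x, fs), x, tolerance = 1e-9)

  t <- (0:15999) / fs
  mid <- 4000:12000
  amp5 <- max(abs(filter_grf(sin(2 * pi * 5 * t), fs)[mid]))
  expect_equal(amp5, butter_zero_phase_gain(5, 30), tolerance = 0.02)
  expect_gt(amp5, 0.98)

  amp500 <- max(abs(filter_grf(sin(2 * pi * 500 * t), fs)[mid]))
  expect_lt(amp500, 0.01)                       # > 99% attenuation
  expect_lt(amp500, butter_zero_phase_gain(500, 30) * 10)

  expect_error(filter_grf(x, 50), "Nyquist|exceed")
})

test_that("filters are linear operators", {
  withr::with_seed(5, {
    a <- rnorm(4000); b <- rnorm(4000)
    lhs <- filter_grf(2 * a + 3 * b, 2000)
    rhs <- 2 * filter_grf(a, 2000) + 3 * filter_grf(b, 2000)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  })
})

test_that("zero-phase filtering introduces no lag", {
  fs <- 2000
  t <- (0:7999) / fs
  pulse <- exp(-((t - 2)^2) / (2 * 0.05^2))       # band-limited Gaussian pulse
  y <- filter_grf(pulse, fs)
  lags <- -30:30
  xc <- vapply(lags, function(l) {
    idx <- 500:7500
    sum(pulse[idx] * y[idx + l])
  }, numeric(1))
  expect_equal(lags[which.max(xc)], 0L)
})

test_that("EMG chain: band-pass, rectify, envelope, normalize", {
  fs <- 2000
  expect_equal(process_emg(numeric(8000), fs), numeric(8000))

  # DC is outside the 30-500 Hz band
  dc <- process_emg(rep(3, 12000), fs)
  expect_lt(max(abs(dc)), 1e-6 * 3)

  # self-normalization: envelope max of the processed signal itself is 1
  t <- (0:15999) / fs
  x <- sin(2 * pi * 100 * t) * 2.5
  env <- process_emg(x, fs, normalizer = 1)
  norm <- max(env)
  expect_equal(max(process_emg(x, fs, normalizer = norm)), 1.0,
               tolerance = 1e-9)
  expect_error(process_emg(x, fs, normalizer = 0), "positive")
  expect_error(process_emg(x, 900), "Nyquist|exceed")
})

test_that("EMG normalizers come from the baseline trial, one per muscle", {
  trial <- make_pulse_trial()
  norms <- compute_emg_normalizer(trial)
  expect_named(norms, c("emg_r_soleus", "emg_r_tibant"))
  expect_true(all(norms > 0))
  expect_false(norms[["emg_r_soleus"]] == norms[["emg_r_tibant"]])
  expect_equal(norms[["emg_r_soleus"]],
               max(process_emg(trial$signals$emg_r_soleus, 2000)),
               tolerance = 1e-12)

  non_base <- make_pulse_trial(baseline = FALSE)
  expect_error(compute_emg_normalizer(non_base), "baseline")

  zero_emg <- make_pulse_trial()
  zero_emg$signals$emg_r_soleus <- numeric(nrow(zero_emg$signals))
  zero_emg$signals$emg_r_tibant <- numeric(nrow(zero_emg$signals))
  expect_error(compute_emg_normalizer(zero_emg), "Degenerate")
})

test_that("heel strikes are rising threshold crossings with a refractory period", {
  fs <- 2000
  expect_identical(detect_heel_strikes(numeric(5000), fs), integer(0))

  # pulses constructed so the crossing sample is known exactly
  trial <- make_pulse_trial(onsets = c(1000, 3100, 5150))
  det <- detect_heel_strikes(trial$signals$grf_r_z, fs, threshold = 30)
  expect_identical(as.integer(det), c(1000L, 3100L, 5150L))

  # chatter around the threshold within 0.1 s collapses to one event
  x <- numeric(4000)
  x[1000 + 0:200] <- 35
  x[1000 + seq(10, 190, by = 20)] <- 25          # dips recross the threshold
  det2 <- detect_heel_strikes(x, fs, threshold = 30, refractory = 0.5)
  expect_identical(length(det2), 1L)

  # brute-force oracle: independent scan honoring the refractory rule
  oracle_detect <- function(x, thr, refr_samples) {
    out <- integer(0); last <- -Inf
    for (i in 2:length(x)) {
      if (x[i - 1] < thr && x[i] >= thr && i - last >= refr_samples) {
        out <- c(out, i); last <- i
      }
    }
    out
  }
  withr::with_seed(7, {
    for (rep in 1:5) {
      x <- pmax(0, rnorm(3000, mean = 20, sd = 15))
      expect_identical(
        as.integer(detect_heel_strikes(x, fs, 30, 0.25)),
        oracle_detect(x, 30, 0.25 * fs))
    }
  })
})

test_that("gait-cycle segmentation is half-open and concatenates exactly", {
  trial <- make_pulse_trial()
  seg <- segment_gait_cycles(trial, c(100L, 300L, 520L))
  expect_identical(nrow(seg), 2L)
  expect_identical(seg$start, c(100L, 300L))
  expect_identical(seg$end, c(300L, 520L))
  expect_identical(vapply(seg$signals, nrow, 1L), c(200L, 220L))
  recat <- dplyr::bind_rows(seg$signals)
  expect_equal(as.data.frame(recat),
               as.data.frame(trial$signals[100:519, ]),
               ignore_attr = TRUE)
  expect_warning(out <- segment_gait_cycles(trial, 100L), "fewer than 2")
  expect_identical(nrow(out), 0L)
})

test_that("fixed windows block-average to the documented length", {
  fs <- 2000
  tr <- make_pulse_trial(n = 8000)
  win <- segment_fixed_windows(tr, window_s = 4, block = 32)
  expect_identical(nrow(win), 1L)
  expect_identical(dim(win$matrix[[1]]), c(250L, 4L))

  tr2 <- make_pulse_trial(n = 16500)
  win2 <- segment_fixed_windows(tr2, window_s = 4, block = 32)
  expect_identical(nrow(win2), 2L)                # 500 trailing samples dropped

  # constant channel stays constant; block-averaging preserves window means
  tr3 <- make_pulse_trial(n = 8000)
  tr3$signals$grf_r_y <- rep(3.25, 8000)
  win3 <- segment_fixed_windows(tr3, 4, 32)
  expect_equal(unname(win3$matrix[[1]][, "grf_r_y"]), rep(3.25, 250))
  expect_equal(mean(win3$matrix[[1]][, "grf_r_z"]),
               mean(tr3$signals$grf_r_z[1:8000]))

  short <- make_pulse_trial(n = 4000, onsets = c(800), pulse_len = 600)
  expect_warning(w0 <- segment_fixed_windows(short, 4, 32), "shorter")
  expect_identical(nrow(w0), 0L)
})

test_that("raw mode bypasses filtering and only rectifies EMG", {
  trial <- make_pulse_trial()
  raw <- preprocess_trial(trial, raw_mode = TRUE)
  expect_identical(raw$signals$grf_r_z, trial$signals$grf_r_z)
  expect_equal(raw$signals$emg_r_soleus, abs(trial$signals$emg_r_soleus))
})
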