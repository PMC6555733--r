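# Synthetic multi-subject walking-data generator.  Emulates two laboratory
# treadmill protocols -- "assisted" (22 channels: 3-axis GRF x 2 feet + 8
# muscles x 2 legs; 9 assistance conditions) and "incline_load" (14 channels:
# 3-axis GRF x 2 feet + 8 muscles x 1 leg; 4 loads x 3 inclines = 12
# conditions) -- with known ground-truth energy expenditure, so the whole
# pipeline is testable without laboratory data.
#
# Signal model (artifact choices, see the methods vignette):
#  * vertical GRF: per-stride stance waveform = sharp 12%-of-peak onset step
#    plus two raised-cosine bumps, scaled by 1.15 * (1 + load) * mass * g;
#    swing is exactly zero.  Strike (stance-onset) samples are recorded as
#    ground truth; additive GRF noise is clamped at 6 sd so it can never
#    cross the 30 N detection threshold.
#  * shear GRF: phase-locked low-amplitude sinusoids inside stance.
#  * EMG: per-muscle raised-cosine activation bursts, phase-locked to the
#    stride and compactly supported away from stride boundaries, amplitude
#    scaled up by incline and load and down by assistance work, multiplied
#    by a carrier (30-500 Hz band-limited noise; a deterministic sinusoid in
#    planted-linear mode) plus additive wideband noise.
#  * breaths: Brockway-inverted at a fixed RER with multiplicative noise.
#
# Two "context" strides of EMG activation (without GRF stance, hence without
# heel strikes) pad each end so every detected gait cycle has identical
# filter context; with all noise at zero this makes every cycle of a trial
# bit-identical, which the planted-linear validation mode relies on.

g_accel <- 9.81
stance_fraction <- 0.62

muscle_table <- function(design) {
  muscles <- tibble(
    muscle = c("soleus", "gastroc", "tibant", "hamstring_med",
               "hamstring_lat", "vastus", "rectus", "glute"),
    phase = c(0.38, 0.41, 0.18, 0.22, 0.25, 0.28, 0.32, 0.35),
    width = c(0.055, 0.05, 0.045, 0.05, 0.05, 0.055, 0.045, 0.05),
    base_amp = c(1.0, 0.9, 0.7, 0.6, 0.6, 0.8, 0.7, 0.5),
    carrier_hz = 85 + 10 * (0:7)
  )
  if (design == "assisted") {
    bind_rows(mutate(muscles, side = "r"), mutate(muscles, side = "l"))
  } else {
    mutate(muscles, side = "r")
  }
}

default_conditions <- function(design) {
  if (design == "assisted") {
    work <- seq(0, 40, by = 5)
    tibble(condition_id = sprintf("assist%02d", work),
           incline_grade = 0, load_fraction = 0, assistance_work = work,
           is_baseline_normal_walk = work == 0)
  } else {
    grid <- tidyr::expand_grid(load_fraction = c(0, 0.1, 0.2, 0.3),
                               incline_grade = c(0, 0.05, 0.10))
    mutate(grid,
           condition_id = sprintf("l%02d_i%02d", round(100 * .data$load_fraction),
                                  round(100 * .data$incline_grade)),
           assistance_work = 0,
           is_baseline_normal_walk =
             .data$load_fraction == 0 & .data$incline_grade == 0)
  }
}

#' Configuration for the synthetic walking-data generator
#'
#' Defaults emulate two laboratory treadmill protocols: walking at a stride rate of
#' 0.93 Hz, signals at 2000 Hz, subject masses of 77.5 +/- 5.6 kg (assisted)
#' or 68.8 +/- 11.5 kg (incline-load), energy-expenditure coefficients that
#' put the assisted conditions near 240--345 W and the incline-load grid in
#' the roughly 185--890 W range, and per-subject random power offsets that
#' make novel-subject estimation measurably harder than novel-condition.
#'
#' With `planted_linear = TRUE` the generator switches to a validation mode
#' in which the condition power is an exact affine function of the binned
#' gait-cycle features: all noise defaults to zero, masses are equal, the
#' cadence is unjittered, subject offsets are disabled and the EMG carrier
#' is a deterministic sinusoid.
#'
#' @param design `"assisted"` (22 channels, 9 assistance conditions) or
#'   `"incline_load"` (14 channels, 4 loads x 3 inclines).
#' @param n_subjects Number of subjects (>= 2).
#' @param conditions Optional condition tibble (`condition_id`,
#'   `incline_grade`, `load_fraction`, `assistance_work`,
#'   `is_baseline_normal_walk`); defaults to the design's grid.
#' @param trial_s Trial duration, s.
#' @param sampling_rate Signal sampling rate, Hz (> 1000).
#' @param cadence_hz Stride (right-heel-strike) rate, Hz.
#' @param cadence_jitter Relative sd of per-stride duration jitter.
#' @param grf_noise_sd Additive GRF noise sd, N (clamped at 6 sd).
#' @param emg_noise_sd Additive wideband EMG noise sd (normalized units).
#' @param breath_cv Multiplicative per-breath noise coefficient of variation.
#' @param ee_base_w_per_kg,ee_incline_w_per_kg,ee_load_w_per_kg
#'   Energy-expenditure model: `P = mass * (base + incline_coef * grade +
#'   load_coef * load) + assist_coef * work + offset`.
#' @param ee_assist_w_per_j Assistance coefficient, W per J/cycle (negative:
#'   assistance lowers cost).
#' @param subject_offset_sd Per-subject power offset sd, W.
#' @param mass_mean,mass_sd Subject mass distribution, kg.
#' @param rer Respiratory exchange ratio used to invert Brockway.
#' @param planted_linear Enable the exact-affine validation mode.
#' @param seed Integer seed; the dataset is fully determined by it.
#' @return A validated config list of class `ee_synth_config`.
#' @export
synthetic_config <- function(design = c("assisted", "incline_load"),
                             n_subjects = 6,
                             conditions = NULL,
                             trial_s = 30,
                             sampling_rate = 2000,
                             cadence_hz = 0.93,
                             cadence_jitter = if (planted_linear) 0 else 0.03,
                             grf_noise_sd = if (planted_linear) 0 else 3,
                             emg_noise_sd = if (planted_linear) 0 else 0.02,
                             breath_cv = if (planted_linear) 0 else 0.05,
                             ee_base_w_per_kg = if (design == "assisted") 4.43 else 2.7,
                             ee_incline_w_per_kg = 55,
                             ee_load_w_per_kg = 16,
                             ee_assist_w_per_j = -2.5,
                             subject_offset_sd = if (planted_linear) 0 else 25,
                             mass_mean = if (design == "assisted") 77.5 else 68.8,
                             mass_sd = if (design == "assisted") 5.6 else 11.5,
                             rer = 0.85,
                             planted_linear = FALSE,
                             seed = 1) {
  design <- match.arg(design)
  if (n_subjects < 2L) abort("n_subjects must be >= 2")
  if (sampling_rate <= 1000) abort("sampling_rate must exceed 1000 Hz")
  if (grf_noise_sd < 0 || emg_noise_sd < 0 || breath_cv < 0)
    abort("noise levels must be >= 0")
  if (is.null(conditions)) conditions <- default_conditions(design)
  if (sum(conditions$is_baseline_normal_walk) != 1L)
    abort("Exactly one condition must be the baseline normal walk")
  structure(list(
    design = design, n_subjects = as.integer(n_subjects),
    conditions = conditions, trial_s = trial_s,
    sampling_rate = sampling_rate, cadence_hz = cadence_hz,
    cadence_jitter = if (planted_linear) 0 else cadence_jitter,
    grf_noise_sd = grf_noise_sd, emg_noise_sd = emg_noise_sd,
    breath_cv = breath_cv,
    ee_base_w_per_kg = ee_base_w_per_kg,
    ee_incline_w_per_kg = ee_incline_w_per_kg,
    ee_load_w_per_kg = ee_load_w_per_kg,
    ee_assist_w_per_j = ee_assist_w_per_j,
    subject_offset_sd = if (planted_linear) 0 else subject_offset_sd,
    mass_mean = mass_mean, mass_sd = if (planted_linear) 0 else mass_sd,
    rer = rer, planted_linear = isTRUE(planted_linear),
    seed = as.integer(seed)), class = "ee_synth_config")
}

raised_cosine <- function(u, center, halfwidth) {
  out <- numeric(length(u))
  inside <- abs(u - center) < halfwidth
  out[inside] <- 0.5 * (1 + cos(pi * (u[inside] - center) / halfwidth))
  out
}

clamped_noise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  pmin(pmax(rnorm(n, sd = sd), -6 * sd), 6 * sd)
}

# One trial's signal channels + planted strike indices.  Consumes RNG.
synth_signals <- function(cfg, mass, cond) {
  fs <- cfg$sampling_rate
  N <- as.integer(round(cfg$trial_s * fs))
  Ls <- as.integer(round(fs / cfg$cadence_hz))
  pad0 <- as.integer(round(0.05 * fs))

  # stride lengths, including 2 context strides at each end
  lens <- integer(0)
  total <- pad0
  repeat {
    L <- as.integer(round(Ls * (1 + if (cfg$cadence_jitter > 0)
      pmin(pmax(rnorm(1, sd = cfg$cadence_jitter), -2.5 * cfg$cadence_jitter),
           2.5 * cfg$cadence_jitter) else 0)))
    if (total + L > N - pad0) break
    lens <- c(lens, L)
    total <- total + L
  }
  n_total <- length(lens)
  if (n_total < 6L)
    abort("Trial too short for two heel strikes plus context strides; increase trial_s")
  onsets <- pad0 + c(0L, cumsum(lens[-n_total])) + 1L
  real <- 3:(n_total - 2L)              # strides with GRF stance
  strikes <- onsets[real]

  A <- 1.15 * (1 + cond$load_fraction) * mass * g_accel
  grf <- list(grf_r_x = numeric(N), grf_r_y = numeric(N), grf_r_z = numeric(N),
              grf_l_x = numeric(N), grf_l_y = numeric(N), grf_l_z = numeric(N))
  add_stance <- function(grf, start, L, side) {
    sl <- as.integer(round(stance_fraction * L))
    idx <- start:(start + sl - 1L)
    idx <- idx[idx >= 1L & idx <= N]
    u <- (idx - start) / sl
    grf[[paste0("grf_", side, "_z")]][idx] <-
      grf[[paste0("grf_", side, "_z")]][idx] +
      A * (0.12 + raised_cosine(u, 0.25, 0.21) + raised_cosine(u, 0.75, 0.21))
    grf[[paste0("grf_", side, "_y")]][idx] <-
      grf[[paste0("grf_", side, "_y")]][idx] - 0.18 * A * sin(2 * pi * u)
    grf[[paste0("grf_", side, "_x")]][idx] <-
      grf[[paste0("grf_", side, "_x")]][idx] + 0.05 * A * sin(pi * u)
    grf
  }
  for (i in real) {
    grf <- add_stance(grf, onsets[i], lens[i], "r")
    grf <- add_stance(grf, onsets[i] + as.integer(round(lens[i] / 2)),
                      lens[i], "l")
  }
  for (nm in names(grf)) grf[[nm]] <- grf[[nm]] + clamped_noise(N, cfg$grf_noise_sd)

  # EMG: activation burst train over ALL strides (incl. context), times carrier
  gain <- max(0.1, 1 + 3 * cond$incline_grade + 1.2 * cond$load_fraction -
                0.01 * cond$assistance_work)
  mt <- muscle_table(cfg$design)
  tvec <- (seq_len(N) - 1L) / fs
  emg <- list()
  for (r in seq_len(nrow(mt))) {
    m <- mt[r, ]
    phase <- m$phase + if (m$side == "l") 0.5 else 0
    act <- numeric(N)
    for (i in seq_len(n_total)) {
      sl <- lens[i]
      idx <- onsets[i]:(onsets[i] + sl - 1L)
      idx <- idx[idx <= N]
      u <- (idx - onsets[i]) / sl
      act[idx] <- act[idx] +
        m$base_amp * gain * raised_cosine(u, phase, m$width)
    }
    if (cfg$planted_linear) {
      carrier <- sin(2 * pi * m$carrier_hz * tvec + r)
    } else {
      carrier <- zero_phase_filter(
        rnorm(N), butter_coeffs(2, c(30, 500), fs, "pass"))
      carrier <- carrier / max(stats::sd(carrier), 1e-12)
    }
    emg[[paste0("emg_", m$side, "_", m$muscle)]] <-
      act * carrier + if (cfg$emg_noise_sd > 0) rnorm(N, sd = cfg$emg_noise_sd)
      else 0
  }
  list(signals = as_tibble(c(grf, emg)), strikes = strikes)
}

synth_breaths <- function(cfg, power_w, trial_s) {
  times <- seq(3, trial_s, by = 3.5)
  if (cfg$breath_cv > 0)
    times <- sort(times + runif(length(times), -0.5, 0.5))
  p <- power_w * (1 + if (cfg$breath_cv > 0)
    pmin(pmax(rnorm(length(times), sd = cfg$breath_cv), -0.9), 3) else 0)
  gas <- invert_brockway(pmax(p, 0), cfg$rer)
  tibble(time = times, vo2 = gas$vo2, vco2 = gas$vco2)
}

interior_cycle_features <- function(trial, normalizers, n_bins = 30) {
  proc <- preprocess_trial(trial, normalizers = normalizers)
  grf <- proc$signals[[right_vertical_grf_name(trial_channels(proc))]]
  strikes <- detect_heel_strikes(grf, proc$sampling_rate)
  cyc <- segment_gait_cycles(proc, strikes)
  mid <- cyc$signals[[max(1L, nrow(cyc) %/% 2L)]]
  bin_cycle(mid, n_bins)
}

#' Generate a synthetic multi-subject walking dataset
#'
#' Builds one trial per subject and condition according to the configured
#' design, with known per-condition metabolic power.  In the default mode
#' the power follows the configured energy-expenditure model plus a
#' per-subject offset; in planted-linear mode it is an exact affine function
#' of the trial's binned gait-cycle features, whose weights are returned.
#' The dataset is fully determined by `cfg$seed`.
#'
#' @param cfg An [synthetic_config()].
#' @return A list:
#' \describe{
#'   \item{trials}{list of [trial_recording()] objects, ordered by subject
#'     then condition id;}
#'   \item{truth}{a list with `labels` (tibble `subject_id`, `condition_id`,
#'     `mass`, `power_w`), `strikes` (named list of planted heel-strike
#'     sample indices per trial, key `"subject/condition"`), `planted`
#'     (weights `w`, intercept `b` in planted-linear mode, else `NULL`), and
#'     the `config`.}
#' }
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "ee_synth_config"))
  conds <- arrange(cfg$conditions, .data$condition_id)
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))

  withr::with_seed(cfg$seed, {
    masses <- pmin(pmax(rnorm(cfg$n_subjects, cfg$mass_mean, cfg$mass_sd),
                        45), 120)
    offsets <- if (cfg$subject_offset_sd > 0)
      rnorm(cfg$n_subjects, sd = cfg$subject_offset_sd) else rep(0, cfg$n_subjects)
    n_chan <- 6L + nrow(muscle_table(cfg$design))
    w_raw <- rnorm(30L * n_chan)

    trials <- list()
    strikes <- list()
    meta <- list()
    for (si in seq_len(cfg$n_subjects)) {
      subj <- subject_meta(subjects[si], masses[si])
      for (ci in seq_len(nrow(conds))) {
        cond <- condition_meta(conds$condition_id[ci],
                               incline_grade = conds$incline_grade[ci],
                               load_fraction = conds$load_fraction[ci],
                               assistance_work = conds$assistance_work[ci],
                               is_baseline_normal_walk =
                                 conds$is_baseline_normal_walk[ci])
        sig <- synth_signals(cfg, masses[si], cond)
        key <- paste(subjects[si], conds$condition_id[ci], sep = "/")
        strikes[[key]] <- sig$strikes
        meta[[key]] <- list(subject = subj, condition = cond,
                            signals = sig$signals, si = si, ci = ci)
      }
    }

    # ground-truth condition power
    labels <- purrr::map_dfr(meta, function(m) tibble(
      subject_id = m$subject$subject_id,
      condition_id = m$condition$condition_id,
      mass = m$subject$mass,
      power_w = m$subject$mass * (cfg$ee_base_w_per_kg +
                                    cfg$ee_incline_w_per_kg * m$condition$incline_grade +
                                    cfg$ee_load_w_per_kg * m$condition$load_fraction) +
        cfg$ee_assist_w_per_j * m$condition$assistance_work + offsets[m$si]))
    planted <- NULL
    if (cfg$planted_linear) {
      # exact affine map from binned features to power
      feats <- list()
      for (s in subjects) {
        base_key <- paste(s, conds$condition_id[conds$is_baseline_normal_walk],
                          sep = "/")
        bm <- meta[[base_key]]
        base_trial <- trial_recording(bm$subject, bm$condition, bm$signals,
                                      tibble(time = 1, vo2 = 0.3, vco2 = 0.25),
                                      cfg$sampling_rate)
        norms <- compute_emg_normalizer(base_trial)
        for (key in names(meta)[startsWith(names(meta), paste0(s, "/"))]) {
          m <- meta[[key]]
          trial <- trial_recording(m$subject, m$condition, m$signals,
                                   tibble(time = 1, vo2 = 0.3, vco2 = 0.25),
                                   cfg$sampling_rate)
          feats[[key]] <- interior_cycle_features(trial, norms)
        }
      }
      F <- do.call(rbind, feats[paste(labels$subject_id, labels$condition_id,
                                      sep = "/")])
      s_raw <- as.numeric(F %*% w_raw)
      spread <- stats::sd(s_raw)
      if (spread < 1e-12) abort("Degenerate planted-linear design")
      w <- w_raw * (60 / spread)
      b <- 343 - mean(s_raw) * (60 / spread)
      labels$power_w <- as.numeric(F %*% w) + b
      planted <- list(w = setNames(w, colnames(F)), b = b)
    }
    if (any(labels$power_w <= 0))
      abort("Configuration yields non-positive condition power")

    for (key in names(meta)) {
      m <- meta[[key]]
      p <- labels$power_w[labels$subject_id == m$subject$subject_id &
                            labels$condition_id == m$condition$condition_id]
      trials[[key]] <- trial_recording(
        m$subject, m$condition, m$signals,
        synth_breaths(cfg, p, cfg$trial_s), cfg$sampling_rate)
    }
    ord <- order(names(trials), method = "radix")
    trials <- trials[ord]
    list(trials = unname(trials),
         truth = list(labels = labels, strikes = strikes,
                      planted = planted, config = cfg))
  })
}
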