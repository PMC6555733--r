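# Signal conditioning follows standard biomechanics practice: 4th-order
# Butterworth filters applied zero-phase (forward-backward) so no channel is
# delayed relative to another.  Zero-phase application squares the magnitude
# response, so quoted attenuations are per-pass.

butter_coeffs <- function(order, cutoff_hz, sampling_rate, type) {
  nyq <- sampling_rate / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq))
    abort(sprintf(
      "Filter cutoff (%s Hz) must lie strictly between 0 and Nyquist (%g Hz)",
      paste(cutoff_hz, collapse = ", "), nyq))
  if (type == "pass" && cutoff_hz[1] >= cutoff_hz[2])
    abort("Bandpass requires low cutoff < high cutoff")
  signal::butter(order, cutoff_hz / nyq, type = type)
}

#' Zero-phase IIR filtering with reflective padding
#'
#' Applies the filter forward then backward (no phase lag; squared magnitude
#' response).  Edge transients are suppressed by odd-reflection padding at
#' each end, sized from the filter's slowest pole so that the zero-state
#' startup transient decays below 1e-14 of signal scale inside the pad.
#'
#' @param x Numeric vector.
#' @param filt A filter object with `b` (numerator) and `a` (denominator)
#'   coefficients, e.g. from `signal::butter()`.
#' @return Filtered vector, same length as `x`.
#' @export
zero_phase_filter <- function(x, filt) {
  b <- as.numeric(filt$b); a <- as.numeric(filt$a)
  n <- length(x)
  # samples for the slowest pole's impulse response to fall below 1e-14
  rmax <- max(Mod(polyroot(rev(a))))
  rmax <- min(rmax, 1 - 1e-9)
  npad <- min(n - 1L, as.integer(ceiling(log(1e-14) / log(rmax))))
  npad <- max(npad, 3L * (max(length(a), length(b)) - 1L))
  npad <- min(npad, n - 1L)
  if (npad > 0L) {
    left  <- 2 * x[1] - x[(npad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - npad)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  # Forward-backward pass applied in the frequency domain: multiply by
  # |H(w)|^2 (zero phase by construction).  With the reflective padding the
  # circular wrap-around transient decays below 1e-14 before reaching the
  # signal, so this matches the two-pass time-domain filter to rounding.
  L <- stats::nextn(length(xp) + npad, c(2L, 3L, 5L))
  xz <- c(xp, numeric(L - length(xp)))
  key <- paste(signif(c(b, a), 15), collapse = ",")
  key <- paste0(key, "|", L)
  mag2 <- .zp_cache[[key]]
  if (is.null(mag2)) {
    w <- exp(-2i * pi * (seq_len(L) - 1L) / L)
    num <- Reduce(function(acc, bk) acc * w + bk, rev(b), init = 0 * w)
    den <- Reduce(function(acc, ak) acc * w + ak, rev(a), init = 0 * w)
    mag2 <- Mod(num / den)^2
    .zp_cache[[key]] <- mag2
  }
  y <- Re(stats::fft(stats::fft(xz) * mag2, inverse = TRUE)) / L
  y[(npad + 1L):(npad + n)]
}

.zp_cache <- new.env(parent = emptyenv())

#' Condition a ground reaction force channel
#'
#' 4th-order Butterworth low-pass at 30 Hz, zero-phase, removing
#' high-frequency noise while passing the gait-frequency content unchanged
#' (DC gain 1).
#'
#' @param x Numeric force samples, N.
#' @param sampling_rate Sampling rate, Hz; must exceed twice the cutoff.
#' @param cutoff_hz Low-pass cutoff, Hz (default 30).
#' @param order Butterworth order (default 4).
#' @return Filtered samples, same length.
#' @export
filter_grf <- function(x, sampling_rate, cutoff_hz = 30, order = 4) {
  if (sampling_rate <= 2 * cutoff_hz)
    abort("sampling_rate must exceed twice the GRF low-pass cutoff")
  zero_phase_filter(x, butter_coeffs(order, cutoff_hz, sampling_rate, "low"))
}

#' EMG linear-envelope processing chain
#'
#' The standard chain: 30--500 Hz band-pass (removes motion artifact and
#' out-of-band noise), full-wave rectification, 6 Hz low-pass (linear
#' envelope), then division by `normalizer` -- the muscle's maximum envelope
#' during the subject's normal walking trial (see
#' [compute_emg_normalizer()]).  All filters 4th-order Butterworth,
#' zero-phase.
#'
#' @param x Numeric EMG samples (arbitrary units).
#' @param sampling_rate Sampling rate, Hz; must exceed 1000 Hz so the 500 Hz
#'   band edge is below Nyquist.
#' @param normalizer Positive scale; use 1 to obtain the unnormalized envelope.
#' @param band Band-pass corner frequencies, Hz.
#' @param envelope_cutoff_hz Envelope low-pass cutoff, Hz.
#' @param order Butterworth order (default 4).
#' @return Normalized envelope, same length; non-negative up to filter ringing.
#' @export
process_emg <- function(x, sampling_rate, normalizer = 1,
                        band = c(30, 500), envelope_cutoff_hz = 6, order = 4) {
  if (sampling_rate <= 2 * band[2])
    abort("sampling_rate must exceed twice the band-pass upper cutoff")
  if (!is.finite(normalizer) || normalizer <= 0)
    abort("normalizer must be positive")
  y <- zero_phase_filter(x, butter_coeffs(order, band, sampling_rate, "pass"))
  y <- abs(y)
  y <- zero_phase_filter(
    y, butter_coeffs(order, envelope_cutoff_hz, sampling_rate, "low"))
  y / normalizer
}

#' Per-muscle EMG normalizers from the baseline normal-walking trial
#'
#' For each EMG channel of the baseline trial, computes the maximum of the
#' processed (band-pass, rectify, low-pass; unnormalized) envelope.  These
#' maxima scale that subject's EMG envelopes in every condition.
#'
#' @param baseline_trial A trial whose condition has
#'   `is_baseline_normal_walk = TRUE`.
#' @inheritParams process_emg
#' @return Named numeric vector, one entry per EMG channel.
#' @export
compute_emg_normalizer <- function(baseline_trial, band = c(30, 500),
                                   envelope_cutoff_hz = 6, order = 4) {
  if (!isTRUE(baseline_trial$condition$is_baseline_normal_walk))
    abort("Normalizers must come from the baseline normal walking trial")
  info <- parse_channel_names(trial_channels(baseline_trial))
  emg <- info$name[info$kind == "emg"]
  if (length(emg) == 0L) abort("Baseline trial has no EMG channels")
  out <- vapply(emg, function(nm) {
    max(process_emg(baseline_trial$signals[[nm]], baseline_trial$sampling_rate,
                    normalizer = 1, band = band,
                    envelope_cutoff_hz = envelope_cutoff_hz, order = order))
  }, numeric(1))
  if (any(out <= 0))
    abort(paste0("Degenerate (non-positive) EMG envelope in baseline channel(s): ",
                 paste(emg[out <= 0], collapse = ", ")))
  out
}

#' Condition every channel of a trial
#'
#' GRF channels pass through [filter_grf()]; EMG channels through
#' [process_emg()] using the per-subject `normalizers`.  With
#' `raw_mode = TRUE` all filtering is bypassed and EMG channels are only
#' rectified (no normalization) -- the "raw" evaluation variant.
#'
#' @param trial A `trial_recording`.
#' @param normalizers Named vector from [compute_emg_normalizer()]; required
#'   unless `raw_mode = TRUE`.
#' @param raw_mode Bypass filtering, rectify EMG only.
#' @return The trial with conditioned signal columns.
#' @export
preprocess_trial <- function(trial, normalizers = NULL, raw_mode = FALSE) {
  info <- parse_channel_names(trial_channels(trial))
  sig <- trial$signals
  for (i in seq_len(nrow(info))) {
    nm <- info$name[i]
    if (raw_mode) {
      if (info$kind[i] == "emg") sig[[nm]] <- abs(sig[[nm]])
    } else if (info$kind[i] == "grf") {
      sig[[nm]] <- filter_grf(sig[[nm]], trial$sampling_rate)
    } else {
      if (is.null(normalizers) || is.na(normalizers[nm]))
        abort(paste0("No EMG normalizer supplied for channel '", nm, "'"))
      sig[[nm]] <- process_emg(sig[[nm]], trial$sampling_rate,
                               normalizer = normalizers[[nm]])
    }
  }
  trial$signals <- sig
  trial
}
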