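#' Synthetic noise-corrupted ECG-like signal
#'
#' A quasi-periodic train of biphasic beat templates (a Gaussian-derivative
#' spike, bandwidth set by `width`) with +/-5 percent uniform jitter on the
#' beat-to-beat intervals, plus white Gaussian noise at the requested RMS.
#' The template energy sits well below a quarter of the sampling rate, so
#' the level-1 details band of a decomposition carries mostly noise while
#' deeper detail levels carry the beats. Ground-truth beat times are
#' returned for event-recovery checks.
#'
#' @param fs sampling frequency in Hz.
#' @param duration record length in seconds (must fit at least 2 beats).
#' @param bpm mean heart rate in beats per minute.
#' @param width beat template width in seconds (the spike occupies about this
#'   much time; spectral peak near `3 / (pi * width)` Hz).
#' @param amplitude beat peak amplitude.
#' @param noise_rms RMS of the additive white noise.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return list with `signal` (a [sampled_signal()]) and `beat_times`
#'   (seconds).
#' @export
synth_ecg <- function(fs = 360, duration = 10, bpm = 72, width = 0.03,
                      amplitude = 1, noise_rms = 0.3, seed = 1) {
  stopifnot(fs > 0, noise_rms >= 0, width > 0, bpm > 0)
  period <- 60 / bpm
  if (duration < 2 * period) stop("duration must cover at least 2 beats")
  set.seed(as.integer(seed))
  n_max <- ceiling(duration / period) + 2
  intervals <- period * (1 + stats::runif(n_max, -0.05, 0.05))
  beats <- period / 2 + cumsum(c(0, intervals))
  beats <- beats[beats < duration - width]
  n <- round(duration * fs)
  t <- seq_len(n) / fs - 1 / fs
  x <- numeric(n)
  sigma <- width / 6
  for (b in beats) {
    idx <- which(abs(t - b) < 4 * width)
    u <- (t[idx] - b) / sigma
    x[idx] <- x[idx] - amplitude * u * exp(0.5 - u^2 / 2)  # peak = amplitude
  }
  x <- x + stats::rnorm(n, 0, noise_rms)
  list(signal = sampled_signal(x, fs), beat_times = beats)
}

# analog band-pass (or low-pass for f1 = 0) shaping prototype for one band
band_shaper <- function(f1, f2, order = 4) {
  stopifnot(f2 > f1, f1 >= 0)
  if (f1 == 0) {
    wc <- 2 * pi * f2
    rational_tf(poles = wc * butterworth_poles(order), gain = wc^order)
  } else {
    m <- order / 2
    w0 <- 2 * pi * sqrt(f1 * f2)
    bw <- 2 * pi * (f2 - f1)
    proto <- butterworth_poles(m)
    poles <- unlist(lapply(proto, function(p) {
      disc <- sqrt(as.complex((p * bw)^2 - 4 * w0^2))
      c((p * bw + disc) / 2, (p * bw - disc) / 2)
    }))
    rational_tf(zeros = rep(0 + 0i, m), poles = poles, gain = bw^m)
  }
}

# fraction of a unit-total-power shaped component's power landing in each
# measurement band (numeric integration of the normalized power response)
band_leak_matrix <- function(bands, fs, order = 4) {
  nb <- nrow(bands)
  f <- seq(1e-3, fs / 2, length.out = 4096)
  L <- matrix(0, nb, nb)
  for (b in seq_len(nb)) {
    h2 <- Mod(freq_resp(band_shaper(bands[b, 1], bands[b, 2], order), f))^2
    tot <- sum(h2)
    for (bp in seq_len(nb)) {
      sel <- f >= bands[bp, 1] & f < bands[bp, 2]
      L[bp, b] <- sum(h2[sel]) / tot
    }
  }
  L
}

#' Synthetic two-state, two-channel EEG-like records
#'
#' Each record alternates between two states ("wake", "sleep") with
#' exponentially distributed dwell times (truncated at one epoch minimum).
#' The signal is a sum of band-limited Gaussian noise components, shaped by
#' the package's own analog band-pass prototypes over the four
#' classification sub-bands (0-3.125, 3.125-6.25, 6.25-12.5, 12.5-25 Hz at
#' 100 Hz), with per-state, per-band RMS targets. Because the shaping
#' filters are not brick-wall, component variances are calibrated through
#' the band-leakage matrix so that the expected measured in-band power
#' equals the requested profile. Per-epoch state labels are assigned by
#' majority occupancy.
#'
#' @param fs sampling frequency in Hz.
#' @param n_records number of records.
#' @param duration record length in seconds (>= 10 epochs).
#' @param epoch_s epoch length in seconds.
#' @param dwell_s mean state dwell time in seconds.
#' @param profiles list with numeric length-4 vectors `wake` and `sleep`:
#'   target RMS per sub-band (arbitrary amplitude units). The defaults give
#'   sleep a dominant slow (0-3.125 Hz) band and wake dominant 6.25-25 Hz
#'   activity, mimicking delta-heavy sleep versus alpha/beta-heavy wake.
#' @param n_channels number of channels; channel k scales the profile by
#'   `0.8^(k-1)` so channels are correlated in structure but not identical.
#' @param seed integer seed.
#' @return list of records, each with `signal` (multi-channel
#'   [sampled_signal()]), `labels` (factor per epoch), and `states`
#'   (data.frame of state intervals); plus attributes `bands`, `profiles`.
#' @export
synth_eeg <- function(fs = 100, n_records = 4, duration = 3000, epoch_s = 30,
                      dwell_s = 300,
                      profiles = list(wake = c(2, 2.5, 5, 4),
                                      sleep = c(9, 4, 2, 1)),
                      n_channels = 2, seed = 1) {
  stopifnot(duration >= 10 * epoch_s, fs > 0, n_channels >= 1)
  stopifnot(all(profiles$wake > 0), all(profiles$sleep > 0))
  bands <- cbind(c(0, fs / 32, fs / 16, fs / 8),
                 c(fs / 32, fs / 16, fs / 8, fs / 4))
  nb <- nrow(bands)
  L <- band_leak_matrix(bands, fs)
  vars <- lapply(profiles, function(p) {
    v <- solve(L, p^2)
    if (any(v <= 0)) stop("band profile not realizable with these shapers")
    v
  })
  set.seed(as.integer(seed))
  n <- round(duration * fs)
  t <- seq_len(n) / fs - 1 / fs
  n_epochs <- floor(duration / epoch_s)
  shapers <- lapply(seq_len(nb), function(b) band_shaper(bands[b, 1], bands[b, 2]))
  records <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    # state switching path
    state <- character(0); bound <- numeric(0)
    cur <- sample(c("wake", "sleep"), 1)
    pos <- 0
    while (pos < duration) {
      dwell <- max(epoch_s, stats::rexp(1, 1 / dwell_s))
      state <- c(state, cur); bound <- c(bound, pos)
      pos <- pos + dwell
      cur <- setdiff(c("wake", "sleep"), cur)
    }
    state_of_t <- state[findInterval(t, bound)]
    value <- matrix(0, n, n_channels)
    for (ch in seq_len(n_channels)) {
      chscale <- 0.8^(ch - 1)
      for (b in seq_len(nb)) {
        comp <- tf_simulate(shapers[[b]], stats::rnorm(n), fs = fs,
                            oversample = 1)$value
        comp <- comp / stats::sd(comp)  # unit total power
        amp <- ifelse(state_of_t == "wake",
                      sqrt(vars$wake[b]), sqrt(vars$sleep[b]))
        value[, ch] <- value[, ch] + chscale * amp * comp
      }
    }
    ep <- floor(t / epoch_s)
    labels <- factor(vapply(seq_len(n_epochs) - 1L, function(e) {
      s <- state_of_t[ep == e]
      names(which.max(table(s)))
    }, character(1)), levels = c("wake", "sleep"))
    records[[r]] <- list(signal = sampled_signal(value, fs),
                         labels = labels,
                         states = data.frame(start = bound, state = state))
  }
  attr(records, "bands") <- bands
  attr(records, "profiles") <- profiles
  records
}
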